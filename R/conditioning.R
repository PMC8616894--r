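#' Scale acquisition parameters to the unit interval
#'
#' TE and TR are divided by the dataset filter bounds (50 ms and 5000 ms by
#' default) so the conditioning vector is `(te/te_max, tr/tr_max, fs)`.
#' Using the filter bounds rather than empirical extrema keeps the scaling
#' stable across dataset subsets.
#'
#' @param te_ms,tr_ms acquisition times in ms, in `(0, te_max]` and
#'   `(0, tr_max]`.
#' @param fs fat-saturation flag (0/1).
#' @param te_max,tr_max scaling denominators.
#' @return numeric length-3 vector `(te_scaled, tr_scaled, fs)`.
#' @export
scale_labels <- function(te_ms, tr_ms, fs, te_max = 50, tr_max = 5000) {
  if (any(te_ms <= 0 | te_ms > te_max))
    stop_arg("te_ms out of (0, ", te_max, "]; filter the records first")
  if (any(tr_ms <= 0 | tr_ms > tr_max))
    stop_arg("tr_ms out of (0, ", tr_max, "]; filter the records first")
  if (!all(fs %in% c(0, 1))) stop_arg("fs must be 0 or 1")
  out <- cbind(te_ms / te_max, tr_ms / tr_max, fs)
  dimnames(out) <- NULL
  out[, , drop = TRUE]
}

#' Invert [scale_labels()]
#'
#' @param v length-3 vector or `n x 3` matrix of scaled labels.
#' @param te_max,tr_max scaling denominators.
#' @return matrix (or vector) of `(te_ms, tr_ms, fs)`.
#' @export
unscale_labels <- function(v, te_max = 50, tr_max = 5000) {
  v <- rbind(v)
  out <- cbind(te_ms = v[, 1] * te_max, tr_ms = v[, 2] * tr_max, fs = v[, 3])
  if (nrow(out) == 1) out[1, ] else out
}

#' Adaptive instance normalization
#'
#' Normalizes every feature map (per sample, per channel) to zero mean and
#' unit standard deviation over its spatial extent, then applies the
#' style-dependent scale `alpha` and bias `beta`:
#' `AdaIN(x, y) = alpha(y) * (x - mu(x)) / sigma(x) + beta(y)`.
#' The standard deviation is stabilized as `sqrt(var + epsilon)`.
#'
#' @param features array `H x W x C x N`.
#' @param style list with `alpha`, `beta`: either length-`C` vectors (shared
#'   across the batch) or `N x C` matrices (per-sample styles).
#' @param epsilon variance stabilizer (default 1e-5).
#' @return array of the same shape.
#' @export
adain <- function(features, style, epsilon = 1e-5) {
  d <- dim(features)
  if (length(d) != 4) stop_arg("features must be an H x W x C x N array")
  C <- d[3]; N <- d[4]
  alpha <- style$alpha; beta <- style$beta
  if (is.null(dim(alpha))) {
    if (length(alpha) != C || length(beta) != C)
      stop_arg("style channel count (", length(alpha),
               ") does not match features (", C, ")")
    alpha <- matrix(alpha, N, C, byrow = TRUE)
    beta <- matrix(beta, N, C, byrow = TRUE)
  } else if (ncol(alpha) != C) {
    stop_arg("style channel count (", ncol(alpha),
             ") does not match features (", C, ")")
  }
  adain_fwd(features, alpha, beta, epsilon)$y
}

# internal forward returning the cache needed for backprop.
# alpha/beta are N x C matrices.
adain_fwd <- function(x, alpha, beta, epsilon = 1e-5) {
  d <- dim(x)
  hw <- d[1] * d[2]
  xm <- matrix(x, hw, d[3] * d[4])
  mu <- colMeans(xm)
  va <- colMeans(xm^2) - mu^2
  s <- sqrt(pmax(va, 0) + epsilon)
  xhat <- (xm - rep(mu, each = hw)) / rep(s, each = hw)
  a <- as.vector(t(alpha))  # channel-major within sample, matches C*N order
  b <- as.vector(t(beta))
  y <- xhat * rep(a, each = hw) + rep(b, each = hw)
  dim(y) <- d
  list(y = y, xhat = xhat, s = s, a = a, dims = d)
}

# backward: gy same shape as x; returns gx plus per-(sample,channel) gradients
# of alpha and beta as N x C matrices
adain_bwd <- function(cache, gy) {
  d <- cache$dims
  hw <- d[1] * d[2]
  g <- matrix(gy, hw, d[3] * d[4])
  galpha <- colSums(g * cache$xhat)
  gbeta <- colSums(g)
  # gradient through instance normalization
  gh <- g * rep(cache$a, each = hw)
  m1 <- colMeans(gh)
  m2 <- colMeans(gh * cache$xhat)
  gx <- (gh - rep(m1, each = hw) - cache$xhat * rep(m2, each = hw)) /
    rep(cache$s, each = hw)
  dim(gx) <- d
  list(gx = gx,
       galpha = matrix(galpha, d[4], d[3], byrow = TRUE),
       gbeta = matrix(gbeta, d[4], d[3], byrow = TRUE))
}

#' Project a label vector to per-channel style parameters
#'
#' The style scale and bias are single affine maps of the scaled label
#' vector: `alpha = Wa %*% label + ba`, `beta = Wb %*% label + bb` -- one
#' layer each, no hidden units. With `Wa = Wb = 0`, `ba = 1`, `bb = 0`
#' (the identity initialization) AdaIN reduces to plain instance
#' normalization for every label.
#'
#' @param label_vector length-3 scaled label, or `n x 3` matrix.
#' @param weights list with `Wa`, `ba`, `Wb`, `bb` (`C x 3` matrices and
#'   length-`C` vectors); see [style_weights()].
#' @return list with `alpha`, `beta` (vectors, or `n x C` matrices).
#' @export
style_projection <- function(label_vector, weights) {
  lv <- rbind(label_vector)
  if (ncol(lv) != 3) stop_arg("label_vector must have length 3")
  alpha <- lv %*% t(weights$Wa) + rep(weights$ba, each = nrow(lv))
  beta <- lv %*% t(weights$Wb) + rep(weights$bb, each = nrow(lv))
  if (nrow(lv) == 1) list(alpha = alpha[1, ], beta = beta[1, ])
  else list(alpha = alpha, beta = beta)
}

#' Identity-initialized style projection weights
#'
#' @param n_channels number of feature channels at the injection site.
#' @return list with zero `Wa`, `Wb`, `ba = 1`, `bb = 0`.
#' @export
style_weights <- function(n_channels) {
  list(Wa = matrix(0, n_channels, 3), ba = rep(1, n_channels),
       Wb = matrix(0, n_channels, 3), bb = rep(0, n_channels))
}
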