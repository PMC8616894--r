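#' Loss weights for GAN training
#'
#' @param omega MS-SSIM share of the reconstruction loss (default 0.84,
#'   balancing the MS-SSIM and L1 terms).
#' @param gamma_r1 R1 gradient-penalty coefficient (default 1).
#' @param lambda_c conditioning-loss weight for unpaired training
#'   (default 10).
#' @param lambda_recon weight of the reconstruction loss against the
#'   adversarial loss (default 100, the pix2pix convention; the
#'   reconstruction term anchors image-to-image training).
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(omega = 0.84, gamma_r1 = 1, lambda_c = 10,
                         lambda_recon = 100) {
  stopifnot(omega >= 0, omega <= 1, gamma_r1 >= 0, lambda_c >= 0)
  structure(list(omega = omega, gamma_r1 = gamma_r1, lambda_c = lambda_c,
                 lambda_recon = lambda_recon), class = "loss_weights")
}

softplus <- function(z) log1p(exp(-abs(z))) + pmax(z, 0)

#' Mean absolute (L1) reconstruction loss
#'
#' @param x,x_prime image batches of identical shape.
#' @return scalar mean absolute difference.
#' @export
l1_loss <- function(x, x_prime) {
  if (!identical(dim(x) %||% length(x), dim(x_prime) %||% length(x_prime)))
    stop_arg("shape mismatch in l1_loss")
  mean(abs(x - x_prime))
}

l1_grad <- function(x, x_prime) {
  g <- sign(x_prime - x) / length(x)
  dim(g) <- dim(x)
  g
}

#' Gaussian SSIM window
#'
#' @param size odd window side (default 11).
#' @param sigma Gaussian sd in pixels (default 1.5).
#' @return normalized 1D kernel (the 2D window is its outer product).
#' @export
gaussian_window <- function(size = 11, sigma = 1.5) {
  r <- seq_len(size) - (size + 1) / 2
  k <- exp(-r^2 / (2 * sigma^2))
  k / sum(k)
}

# local Gaussian-window statistics over the valid region; x, y are
# H x W x C x N arrays
.ssim_stats <- function(x, y, k) {
  mx <- cpp_sepconv_valid(x, k)
  my <- cpp_sepconv_valid(y, k)
  sxx <- cpp_sepconv_valid(x * x, k) - mx * mx
  syy <- cpp_sepconv_valid(y * y, k) - my * my
  sxy <- cpp_sepconv_valid(x * y, k) - mx * my
  list(mx = mx, my = my, sxx = sxx, syy = syy, sxy = sxy)
}

# mean contrast-structure term and its gradient w.r.t. y
.cs_mean <- function(x, y, k, c2, want_grad = FALSE) {
  st <- .ssim_stats(x, y, k)
  A2 <- 2 * st$sxy + c2
  B2 <- st$sxx + st$syy + c2
  cs <- A2 / B2
  nw <- length(cs)
  if (!want_grad) return(list(value = mean(cs)))
  P <- 2 / B2
  Q <- 2 * cs / B2
  g <- (x * cpp_sepconv_full(P, k) - cpp_sepconv_full(P * st$mx, k) -
        y * cpp_sepconv_full(Q, k) + cpp_sepconv_full(Q * st$my, k)) / nw
  list(value = mean(cs), grad = g)
}

# mean full SSIM (luminance x contrast-structure) and gradient w.r.t. y
.ssim_mean <- function(x, y, k, c1, c2, want_grad = FALSE) {
  st <- .ssim_stats(x, y, k)
  A1 <- 2 * st$mx * st$my + c1
  B1 <- st$mx^2 + st$my^2 + c1
  A2 <- 2 * st$sxy + c2
  B2 <- st$sxx + st$syy + c2
  l <- A1 / B1
  cs <- A2 / B2
  s <- l * cs
  nw <- length(s)
  if (!want_grad) return(list(value = mean(s), map = s))
  dmu <- (2 / B1) * cs * (st$mx - st$my * l)
  P <- 2 * l / B2
  Q <- 2 * l * cs / B2
  g <- (cpp_sepconv_full(dmu, k) +
        x * cpp_sepconv_full(P, k) - cpp_sepconv_full(P * st$mx, k) -
        y * cpp_sepconv_full(Q, k) + cpp_sepconv_full(Q * st$my, k)) / nw
  list(value = mean(s), grad = g, map = s)
}

ms_ssim_weights <- function(n_scales) {
  w5 <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  if (n_scales > 5) stop_arg("n_scales must be <= 5")
  w <- w5[seq_len(n_scales)]
  w / sum(w)
}

# largest number of dyadic scales (max 5) the image side supports
auto_n_scales <- function(side, window = 11) {
  m <- 1
  while (m < 5 && side >= 2^m * window) m <- m + 1
  m
}

#' Multi-scale structural similarity (MS-SSIM)
#'
#' Contrast/structure terms at each of `n_scales` dyadic downsamplings
#' (2x2 average pooling between scales), luminance at the coarsest scale
#' only, combined as a weighted geometric mean with the standard 5-scale
#' exponents (renormalized to sum 1 when fewer scales are used; for 64 px
#' images three scales fit the 11 px window). Negative per-scale terms are
#' clamped at a small positive floor before exponentiation.
#'
#' @param x,x_prime image batches (`H x W x C x N` arrays or matrices).
#' @param n_scales number of dyadic scales; `NULL` picks the largest number
#'   (up to 5) the image side supports.
#' @param window,sigma Gaussian window size and sd (11, 1.5).
#' @param data_range dynamic range L of the images (2 for `[-1, 1]`);
#'   `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2`.
#' @return scalar: the weighted geometric mean in (0, 1] for several
#'   scales; with `n_scales = 1` this is exactly windowed SSIM, in
#'   `[-1, 1]`.
#' @export
ms_ssim <- function(x, x_prime, n_scales = NULL, window = 11, sigma = 1.5,
                    data_range = 2) {
  ms_ssim_internal(as_batch(x), as_batch(x_prime), n_scales, window, sigma,
                   data_range, want_grad = FALSE)$value
}

ms_ssim_internal <- function(x, y, n_scales, window, sigma, data_range,
                             want_grad) {
  side <- min(dim(x)[1], dim(x)[2])
  if (is.null(n_scales)) n_scales <- auto_n_scales(side, window)
  need <- 2^(n_scales - 1) * window
  if (side < need)
    stop_arg("image side ", side, " too small for ", n_scales,
             " scales; need at least ", need)
  k <- gaussian_window(window, sigma)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  w <- ms_ssim_weights(n_scales)
  eps <- 1e-8
  terms <- numeric(n_scales)
  grads <- vector("list", n_scales)
  xs <- x; ys <- y
  for (j in seq_len(n_scales)) {
    r <- if (j < n_scales) .cs_mean(xs, ys, k, c2, want_grad)
         else .ssim_mean(xs, ys, k, c1, c2, want_grad)
    terms[j] <- r$value
    if (want_grad) grads[[j]] <- r$grad
    if (j < n_scales) {
      xs <- cpp_avgpool2_fwd(xs)
      ys <- cpp_avgpool2_fwd(ys)
    }
  }
  if (n_scales == 1) {
    # single scale is plain windowed SSIM: no geometric combination, so the
    # sign is preserved exactly
    if (!want_grad) return(list(value = terms[1], terms = terms))
    return(list(value = terms[1], grad = grads[[1]], terms = terms))
  }
  tcl <- pmax(terms, eps)
  value <- prod(tcl^w)
  if (!want_grad) return(list(value = value, terms = terms))
  g <- array(0, dim(x))
  for (j in seq_len(n_scales)) {
    if (terms[j] < eps) next  # clamped term: locally flat
    gj <- grads[[j]] * (value * w[j] / tcl[j])
    jj <- j
    while (jj > 1) {
      d <- dim(gj)
      gj <- cpp_avgpool2_bwd(gj, d[1] * 2, d[2] * 2)
      jj <- jj - 1
    }
    g <- g + gj
  }
  list(value = value, grad = g, terms = terms)
}

#' Weighted L1 / MS-SSIM reconstruction loss
#'
#' `omega * (1 - MS-SSIM(x, x')) + (1 - omega) * L1(x, x')`.
#'
#' @param x,x_prime image batches of identical shape.
#' @param weights a [loss_weights()] (only `omega` is used).
#' @param n_scales forwarded to [ms_ssim()].
#' @return scalar loss (0 iff the batches are identical).
#' @export
recon_loss <- function(x, x_prime, weights = loss_weights(), n_scales = NULL) {
  if (!identical(dim(as_batch(x)), dim(as_batch(x_prime))))
    stop_arg("shape mismatch in recon_loss")
  om <- weights$omega
  ms <- if (om > 0) ms_ssim(x, x_prime, n_scales = n_scales) else 1
  om * (1 - ms) + (1 - om) * l1_loss(x, x_prime)
}

# value + gradient w.r.t. x_prime, used by the training loop
recon_grad <- function(x, x_prime, weights, n_scales = NULL) {
  om <- weights$omega
  if (om > 0) {
    r <- ms_ssim_internal(as_batch(x), as_batch(x_prime), n_scales, 11, 1.5, 2,
                          want_grad = TRUE)
    v <- om * (1 - r$value) + (1 - om) * l1_loss(x, x_prime)
    g <- -om * r$grad + (1 - om) * l1_grad(x, x_prime)
  } else {
    v <- l1_loss(x, x_prime)
    g <- l1_grad(x, x_prime)
  }
  dim(g) <- dim(as_batch(x))
  list(value = v, grad = g)
}

#' Non-saturating adversarial losses
#'
#' Softplus form of the non-saturating GAN objective on raw (pre-sigmoid)
#' scores: `d_loss = E[softplus(-D(real))] + E[softplus(D(fake))]`,
#' `g_loss = E[softplus(-D(fake))]`.
#'
#' @param d_real,d_fake raw discriminator scores.
#' @return list with `g_loss` and `d_loss`.
#' @export
nonsat_gan_losses <- function(d_real, d_fake) {
  list(g_loss = mean(softplus(-d_fake)),
       d_loss = mean(softplus(-d_real)) + mean(softplus(d_fake)))
}

#' R1 gradient penalty on real samples
#'
#' `(gamma/2) * E_n ||grad_x D(x_n)||^2`, the zero-centred gradient penalty
#' evaluated on the real batch only.
#'
#' @param discriminator an object with an `$input_grad(x)` method (e.g. from
#'   [build_discriminator()]) returning `list(value, grad)` for per-sample
#'   scores.
#' @param real_batch image batch (`H x W x 1 x N` or matrix).
#' @param weights a [loss_weights()] (uses `gamma_r1`).
#' @return scalar penalty.
#' @export
r1_penalty <- function(discriminator, real_batch, weights = loss_weights()) {
  x <- as_batch(real_batch)
  g <- discriminator$input_grad(x)$grad
  n <- dim(x)[4]
  sq <- sum(g^2) / n  # per-sample squared norm, batch averaged
  weights$gamma_r1 / 2 * sq
}

#' Cycle-consistency loss
#'
#' `E||G(F(g)) - g||_1 + E||F(G(t)) - t||_1` for translators `G` (A to B)
#' and `F` (B to A). In conditioned training a single generator serves as
#' both directions, invoked with swapped source/target labels.
#'
#' @param bundle list with translator functions `G` and `F`, each mapping an
#'   image batch to an image batch.
#' @param g_batch,t_batch image batches from the two domains.
#' @return scalar loss.
#' @export
cycle_loss <- function(bundle, g_batch, t_batch) {
  if (is.null(bundle$G) || is.null(bundle$F))
    stop_arg("cycle training requires both generator directions (G and F)")
  l1_loss(bundle$G(bundle$F(g_batch)), g_batch) +
    l1_loss(bundle$F(bundle$G(t_batch)), t_batch)
}

#' Auxiliary-classifier conditioning loss
#'
#' Mean squared error over the scaled TE and TR predictions (averaged over
#' the two parameters) plus binary cross-entropy (with logits) over the
#' fat-saturation prediction.
#'
#' @param ac_prediction length-3 vector or `N x 3` matrix
#'   `(te_scaled, tr_scaled, fs_logit)`.
#' @param target_label scaled target labels, same shape.
#' @return scalar loss (0 for perfect predictions with saturated FS logits).
#' @export
conditioning_loss <- function(ac_prediction, target_label) {
  p <- rbind(ac_prediction)
  y <- rbind(target_label)
  if (any(!is.finite(p[, 1:2]))) stop_arg("non-finite TE/TR predictions")
  mse <- mean(((p[, 1] - y[, 1])^2 + (p[, 2] - y[, 2])^2) / 2)
  z <- p[, 3]
  bce <- mean(softplus(z) - y[, 3] * z)
  mse + bce
}

# gradient of conditioning_loss w.r.t. the prediction matrix
conditioning_grad <- function(ac_prediction, target_label) {
  p <- rbind(ac_prediction)
  y <- rbind(target_label)
  n <- nrow(p)
  g <- cbind((p[, 1] - y[, 1]) / n,
             (p[, 2] - y[, 2]) / n,
             (1 / (1 + exp(-p[, 3])) - y[, 3]) / n)
  g
}
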