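# Minimal reverse-mode tape used by the networks. Values live in "node"
# environments; every op appends a node whose $bwd closure scatters the
# node's accumulated gradient to its parents (and to layer parameter
# gradients). The graph is tiny (tens of nodes) next to the cost of the
# convolutions, so plain R environments are fine.

ad_tape <- function(inference = FALSE) {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$inference <- inference
  t
}

ad_node <- function(tape, val, bwd = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$bwd <- bwd
  if (!is.null(tape)) tape$nodes[[length(tape$nodes) + 1L]] <- n
  n
}

ad_acc <- function(n, g) {
  n$grad <- if (is.null(n$grad)) g else n$grad + g
  invisible(NULL)
}

ad_input <- function(tape, val) ad_node(tape, val)

# run the backward sweep from the final node, seeded with `seed`
ad_backward <- function(tape, out, seed) {
  ad_acc(out, seed)
  for (i in rev(seq_along(tape$nodes))) {
    n <- tape$nodes[[i]]
    if (!is.null(n$grad) && !is.null(n$bwd)) n$bwd(n$grad)
  }
  invisible(NULL)
}

ad_conv <- function(tape, xn, L) {
  x <- xn$val
  y <- cpp_conv2d_fwd(x, L$w, L$b, L$stride, L$pad)
  ad_node(tape, y, bwd = function(g) {
    # skip gradients nobody consumes: parameter grads of frozen layers /
    # no-param-grad probes, input grads of terminal input nodes
    need_gw <- !(isTRUE(tape$no_param_grads) || isTRUE(L$frozen))
    need_gx <- !is.null(xn$bwd) || isTRUE(xn$want_grad)
    rb <- cpp_conv2d_bwd(x, L$w, g, L$stride, L$pad, need_gx, need_gw)
    if (need_gw) {
      L$gw <- L$gw + rb$gw
      L$gb <- L$gb + rb$gb
    }
    if (need_gx) ad_acc(xn, rb$gx)
  })
}

ad_lrelu <- function(tape, xn, slope = 0.2) {
  x <- xn$val
  y <- cpp_lrelu_fwd(x, slope)
  ad_node(tape, y, bwd = function(g) ad_acc(xn, cpp_lrelu_bwd(x, g, slope)))
}

ad_tanh <- function(tape, xn) {
  y <- tanh(xn$val)
  ad_node(tape, y, bwd = function(g) ad_acc(xn, g * (1 - y^2)))
}

ad_add <- function(tape, an, bn) {
  ad_node(tape, an$val + bn$val, bwd = function(g) {
    ad_acc(an, g)
    ad_acc(bn, g)
  })
}

# add a fixed (non-differentiated) array, e.g. the identity image route
ad_add_const <- function(tape, an, const) {
  ad_node(tape, an$val + const, bwd = function(g) ad_acc(an, g))
}

# clipped atanh of the input image (the identity residual route of the
# generator); gradient is 1/(1-x^2) inside the clip, 0 outside
ad_atanh_clip <- function(tape, xn, lim = 0.999) {
  x <- xn$val
  xc <- pmin(pmax(x, -lim), lim)
  y <- atanh(xc)
  dim(y) <- dim(x)
  d <- (abs(x) < lim) / (1 - xc^2)
  ad_node(tape, y, bwd = function(g) ad_acc(xn, g * d))
}

ad_concat <- function(tape, an, bn) {
  da <- dim(an$val); db <- dim(bn$val)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- an$val
  y[, , da[3] + seq_len(db[3]), ] <- bn$val
  ad_node(tape, y, bwd = function(g) {
    ad_acc(an, g[, , seq_len(da[3]), , drop = FALSE])
    ad_acc(bn, g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

ad_upsample2 <- function(tape, xn) {
  ad_node(tape, cpp_upsample2_fwd(xn$val),
          bwd = function(g) ad_acc(xn, cpp_upsample2_bwd(g)))
}

# AdaIN with label-projected styles. labels: N x 3 matrix, or NULL to gate
# the injection off (plain instance normalization, no projection gradients).
ad_adain <- function(tape, xn, L, labels) {
  d <- dim(xn$val)
  if (is.null(labels)) {
    alpha <- matrix(1, d[4], d[3])
    beta <- matrix(0, d[4], d[3])
  } else {
    alpha <- labels %*% t(L$Wa) + rep(L$ba, each = nrow(labels))
    beta <- labels %*% t(L$Wb) + rep(L$bb, each = nrow(labels))
  }
  cache <- adain_fwd(xn$val, alpha, beta, L$epsilon)
  ad_node(tape, cache$y, bwd = function(g) {
    r <- adain_bwd(cache, g)
    if (!is.null(labels) && !isTRUE(tape$no_param_grads) && !isTRUE(L$frozen)) {
      L$gWa <- L$gWa + t(r$galpha) %*% labels
      L$gba <- L$gba + colSums(r$galpha)
      L$gWb <- L$gWb + t(r$gbeta) %*% labels
      L$gbb <- L$gbb + colSums(r$gbeta)
    }
    ad_acc(xn, r$gx)
  })
}

# spatial global mean: H x W x C x N -> N x C matrix
ad_global_mean <- function(tape, xn) {
  d <- dim(xn$val)
  hw <- d[1] * d[2]
  y <- t(matrix(colMeans(matrix(xn$val, hw, d[3] * d[4])), d[3], d[4]))
  ad_node(tape, y, bwd = function(g) {
    gx <- rep(as.vector(t(g)) / hw, each = hw)
    dim(gx) <- d
    ad_acc(xn, gx)
  })
}

# flatten spatial maps: H x W x C x N -> N x (H*W*C)
ad_flatten <- function(tape, xn) {
  d <- dim(xn$val)
  p <- prod(d[1:3])
  y <- t(matrix(xn$val, p, d[4]))
  ad_node(tape, y, bwd = function(g) {
    gx <- t(g)
    dim(gx) <- d
    ad_acc(xn, gx)
  })
}

# dense layer on N x din matrices
ad_dense <- function(tape, xn, L) {
  x <- xn$val
  y <- x %*% L$w + rep(L$b, each = nrow(x))
  ad_node(tape, y, bwd = function(g) {
    if (!isTRUE(tape$no_param_grads) && !isTRUE(L$frozen)) {
      L$gw <- L$gw + t(x) %*% g
      L$gb <- L$gb + colSums(g)
    }
    ad_acc(xn, g %*% t(L$w))
  })
}

# ---- parameter layers -------------------------------------------------------

new_conv_layer <- function(cin, cout, k = 3, stride = 1,
                           pad = (k - 1) %/% 2, init = c("he", "zero")) {
  init <- match.arg(init)
  L <- new.env(parent = emptyenv())
  sdv <- if (init == "zero") 0 else sqrt(2 / (k * k * cin))
  L$w <- array(rnorm(k * k * cin * cout, 0, sdv), c(k, k, cin, cout))
  L$b <- rep(0, cout)
  L$gw <- array(0, dim(L$w)); L$gb <- rep(0, cout)
  L$stride <- stride; L$pad <- pad
  L$param_names <- c("w", "b")
  L
}

new_dense_layer <- function(din, dout, init = c("he", "zero")) {
  init <- match.arg(init)
  L <- new.env(parent = emptyenv())
  sdv <- if (init == "zero") 0 else sqrt(2 / din)
  L$w <- matrix(rnorm(din * dout, 0, sdv), din, dout)
  L$b <- rep(0, dout)
  L$gw <- matrix(0, din, dout); L$gb <- rep(0, dout)
  L$param_names <- c("w", "b")
  L
}

# identity-initialized style projections (alpha ~ 1, beta ~ 0 at start)
new_adain_layer <- function(C, epsilon = 1e-5) {
  L <- new.env(parent = emptyenv())
  L$Wa <- matrix(0, C, 3); L$ba <- rep(1, C)
  L$Wb <- matrix(0, C, 3); L$bb <- rep(0, C)
  L$gWa <- matrix(0, C, 3); L$gba <- rep(0, C)
  L$gWb <- matrix(0, C, 3); L$gbb <- rep(0, C)
  L$epsilon <- epsilon
  L$param_names <- c("Wa", "ba", "Wb", "bb")
  L
}

grad_name <- function(p) paste0("g", p)

zero_grads <- function(layers) {
  for (L in layers)
    for (p in L$param_names) {
      g <- L[[grad_name(p)]]
      L[[grad_name(p)]] <- g * 0
    }
  invisible(NULL)
}

# flat copy of all parameters of a layer list (used by EMA and checkpoints)
get_params <- function(layers) {
  out <- list()
  for (nm in names(layers)) {
    L <- layers[[nm]]
    for (p in L$param_names) out[[paste0(nm, ".", p)]] <- L[[p]]
  }
  out
}

set_params <- function(layers, params) {
  for (nm in names(layers)) {
    L <- layers[[nm]]
    for (p in L$param_names) L[[p]] <- params[[paste0(nm, ".", p)]]
  }
  invisible(NULL)
}

count_params <- function(layers) {
  sum(vapply(get_params(layers), length, integer(1)))
}
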