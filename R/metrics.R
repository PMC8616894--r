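#' Normalized mean squared error
#'
#' `||x - x'||^2 / ||x||^2`. Note the asymmetry: the first argument is the
#' ground truth that normalizes the error.
#'
#' @param x ground-truth image.
#' @param x_prime reconstructed image.
#' @return scalar >= 0.
#' @export
nmse <- function(x, x_prime) {
  den <- sum(x^2)
  if (den == 0) stop_arg("nmse undefined: ground truth has zero norm")
  sum((x - x_prime)^2) / den
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(MAX^2 / MSE)` where `MAX` is the maximum pixel value range over
#' the *pair* (joint max minus joint min), not a fixed data range. Identical
#' images yield `+Inf` with a warning; evaluation aggregates exclude such
#' pairs.
#'
#' @param x,x_prime images of identical shape.
#' @return PSNR in decibels.
#' @export
psnr <- function(x, x_prime) {
  mse <- mean((x - x_prime)^2)
  if (mse == 0) {
    warning("identical images: PSNR is infinite and excluded from aggregates")
    return(Inf)
  }
  mx <- max(x, x_prime) - min(x, x_prime)
  10 * log10(mx^2 / mse)
}

#' Structural similarity index
#'
#' With `windowed = TRUE` (the default and the common convention) the SSIM
#' map is computed with an 11x11 Gaussian window (sd 1.5) and averaged over
#' the valid region; with `windowed = FALSE` the formula is evaluated once
#' on the global image statistics (population moments).
#'
#' @param x,x_prime images of identical shape.
#' @param windowed locally windowed (default) or global statistics.
#' @param data_range dynamic range L for the stabilizers
#'   `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2`; default 2 for `[-1, 1]` images.
#' @param window,sigma window parameters for the windowed mode.
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(x, x_prime, windowed = TRUE, data_range = 2,
                 window = 11, sigma = 1.5) {
  if (!identical(dim(x) %||% length(x), dim(x_prime) %||% length(x_prime)))
    stop_arg("shape mismatch in ssim")
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  if (windowed) {
    k <- gaussian_window(window, sigma)
    return(.ssim_mean(as_batch(x), as_batch(x_prime), k, c1, c2)$value)
  }
  n <- length(x)
  mx <- mean(x); my <- mean(x_prime)
  vx <- mean(x^2) - mx^2
  vy <- mean(x_prime^2) - my^2
  cxy <- mean(x * x_prime) - mx * my
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

#' Evaluate reconstruction quality over image pairs
#'
#' Translates every pair's source image to the target's acquisition label
#' and scores the synthesis against the target ground truth with NMSE, PSNR
#' and SSIM, aggregated as mean +/- sd. Pairs with infinite PSNR are
#' excluded from the PSNR aggregate.
#'
#' @param pairs list of `image_pair` objects (see [dataset_pairs()]).
#' @param translator function `(image, y_source, y_target) -> image`; e.g.
#'   `function(im, ys, yt) translate(gen, im, ys, yt)`, or the identity
#'   translator `function(im, ys, yt) im` as a do-nothing baseline.
#' @return an `evaluation_report`: list with `per_pair` (data.frame) and
#'   `summary` (mean/sd per metric), `convention` recording the intensity
#'   scale metrics are computed on.
#' @export
evaluate_reconstruction <- function(pairs, translator) {
  if (length(pairs) == 0) stop_arg("pairs must be nonempty")
  rows <- lapply(pairs, function(p) {
    ys <- scale_labels(p$source$label$te_ms, p$source$label$tr_ms, p$source$label$fs)
    yt <- scale_labels(p$target$label$te_ms, p$target$label$tr_ms, p$target$label$fs)
    syn <- translator(p$source$image, ys, yt)
    data.frame(pair_key = p$pair_key,
               nmse = nmse(p$target$image, syn),
               psnr = suppressWarnings(psnr(p$target$image, syn)),
               ssim = ssim(p$target$image, syn))
  })
  per <- do.call(rbind, rows)
  fin <- is.finite(per$psnr)
  if (!all(fin))
    warning(sum(!fin), " pair(s) with infinite PSNR excluded from the aggregate")
  summ <- data.frame(
    metric = c("nmse", "psnr", "ssim"),
    mean = c(mean(per$nmse), mean(per$psnr[fin]), mean(per$ssim)),
    sd = c(sd(per$nmse), sd(per$psnr[fin]), sd(per$ssim)))
  structure(list(per_pair = per, summary = summ,
                 convention = "images in [-1,1]; PSNR MAX over the joint pair range"),
            class = "evaluation_report")
}

#' Evaluate conditioning fidelity with the auxiliary classifier
#'
#' Translates every source to its paired target label, lets the AC read the
#' acquisition parameters off the synthetic image, and reports the mean
#' absolute TE and TR errors (in ms, after unscaling) and the
#' fat-saturation accuracy.
#'
#' @param pairs list of `image_pair` objects.
#' @param translator function `(image, y_source, y_target) -> image`.
#' @param ac a trained [build_aux_classifier()] model (or any object with a
#'   `$predict(images)` method returning `(te_scaled, tr_scaled, fs_logit)`
#'   rows). An untrained AC is a configuration error.
#' @return an `evaluation_report` with per-pair errors and aggregate
#'   MAE +/- sd plus FS accuracy (percent).
#' @export
evaluate_conditioning <- function(pairs, translator, ac) {
  if (length(pairs) == 0) stop_arg("pairs must be nonempty")
  if (inherits(ac, "aux_classifier") && !isTRUE(ac$trained))
    stop_arg("auxiliary classifier is untrained; run pretrain_ac() first")
  rows <- lapply(pairs, function(p) {
    ys <- scale_labels(p$source$label$te_ms, p$source$label$tr_ms, p$source$label$fs)
    yt <- scale_labels(p$target$label$te_ms, p$target$label$tr_ms, p$target$label$fs)
    syn <- translator(p$source$image, ys, yt)
    pr <- rbind(ac$predict(syn))[1, ]
    est <- unscale_labels(c(pr[1], pr[2], as.numeric(pr[3] > 0)))
    data.frame(pair_key = p$pair_key,
               te_err_ms = abs(est["te_ms"] - p$target$label$te_ms),
               tr_err_ms = abs(est["tr_ms"] - p$target$label$tr_ms),
               fs_correct = est["fs"] == p$target$label$fs)
  })
  per <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("te_mae_ms", "tr_mae_ms", "fs_accuracy_pct"),
    mean = c(mean(per$te_err_ms), mean(per$tr_err_ms), 100 * mean(per$fs_correct)),
    sd = c(sd(per$te_err_ms), sd(per$tr_err_ms), NA))
  structure(list(per_pair = per, summary = summ,
                 convention = "TE/TR errors in ms after unscaling"),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", nrow(x$per_pair), "pairs\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-16s %8.4f%s\n", x$summary$metric[i], x$summary$mean[i],
                if (is.na(x$summary$sd[i])) "" else
                  sprintf(" +/- %.4f", x$summary$sd[i])))
  invisible(x)
}

#' Compare a metric between two evaluation reports
#'
#' Two-sample t test on the per-pair values of one metric, the conventional
#' check of whether one model's reconstruction quality differs
#' significantly from another's.
#'
#' @param a,b `evaluation_report` objects.
#' @param metric column of the per-pair table (`"nmse"`, `"psnr"`,
#'   `"ssim"`, ...).
#' @return the `htest` object from [stats::t.test()].
#' @export
compare_reports <- function(a, b, metric = "ssim") {
  t.test(a$per_pair[[metric]], b$per_pair[[metric]])
}
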