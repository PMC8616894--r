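#' Generator configuration
#'
#' The generator is a residual U-Net: a strided stem, one residual block per
#' encoder level with a strided downsampling convolution between levels, a
#' bottleneck residual block, and a mirrored decoder (nearest-neighbour
#' upsampling + convolution, skip concatenation, residual block). Every
#' residual block normalizes with AdaIN; encoder blocks consume the source
#' labels, bottleneck and decoder blocks the target labels. Style
#' projections are always built -- the `inject_*` flags only gate whether
#' labels reach them -- so parameter count is identical across model
#' variants. The output convolution is zero-initialized and a fixed
#' `atanh`-route adds the input image before the final `tanh`, so an
#' untrained generator is the identity map.
#'
#' @param filters encoder filter sizes per level (decoder mirrors them
#'   reversed). Default is the desk scale `c(16, 32, 64)`; the full scale
#'   used on clinical images is `c(64, 128, 256, 512)`.
#' @param base_size input side length; must be divisible by
#'   `2^length(filters)`.
#' @param inject_source_labels,inject_target_labels gate the encoder /
#'   decoder label injection.
#' @return a `generator_config` list.
#' @export
generator_config <- function(filters = c(16, 32, 64), base_size = 64,
                             inject_source_labels = TRUE,
                             inject_target_labels = TRUE) {
  structure(list(filters = filters, base_size = base_size,
                 inject_source_labels = inject_source_labels,
                 inject_target_labels = inject_target_labels),
            class = "generator_config")
}

#' Build the AdaIN-conditioned residual U-Net generator
#'
#' @param config a [generator_config()].
#' @param seed optional seed for weight initialization.
#' @return an object of class `generator` with a `$forward` closure mapping
#'   `(image batch, source labels, target labels)` to an image batch in
#'   `[-1, 1]`.
#' @export
build_generator <- function(config = generator_config(), seed = NULL) {
  f <- config$filters
  L <- length(f)
  if (config$base_size %% (2^L) != 0)
    stop_arg("base_size must be divisible by 2^", L, " (= ", 2^L, ")")
  build <- function() {
    layers <- list(stem = new_conv_layer(1, f[1], stride = 2))
    add_res <- function(prefix, cin, cout) {
      layers[[paste0(prefix, ".conv1")]] <<- new_conv_layer(cin, cout)
      layers[[paste0(prefix, ".ad1")]] <<- new_adain_layer(cout)
      layers[[paste0(prefix, ".conv2")]] <<- new_conv_layer(cout, cout)
      layers[[paste0(prefix, ".ad2")]] <<- new_adain_layer(cout)
      if (cin != cout)
        layers[[paste0(prefix, ".short")]] <<- new_conv_layer(cin, cout, k = 1, pad = 0)
    }
    for (l in seq_len(L - 1)) {
      add_res(paste0("enc", l), f[l], f[l])
      layers[[paste0("down", l)]] <- new_conv_layer(f[l], f[l + 1], stride = 2)
    }
    add_res("bott", f[L], f[L])
    for (l in rev(seq_len(L - 1))) {
      layers[[paste0("up", l)]] <- new_conv_layer(f[l + 1], f[l])
      add_res(paste0("dec", l), 2 * f[l], f[l])
    }
    layers$final <- new_conv_layer(f[1], f[1])
    layers$out <- new_conv_layer(f[1], 1, init = "zero")
    layers
  }
  layers <- if (is.null(seed)) build() else
    with_seed(substream_seed(seed, "gen_init"), build())

  g <- new.env(parent = emptyenv())
  g$layers <- layers
  g$config <- config
  g$ema <- NULL
  class(g) <- "generator"
  g$forward <- function(x, ys, yt, tape = ad_tape()) {
    gen_forward(g, x, ys, yt, tape)
  }
  g
}

res_fwd <- function(tape, xn, layers, prefix, labels) {
  h <- ad_conv(tape, xn, layers[[paste0(prefix, ".conv1")]])
  h <- ad_adain(tape, h, layers[[paste0(prefix, ".ad1")]], labels)
  h <- ad_lrelu(tape, h)
  h <- ad_conv(tape, h, layers[[paste0(prefix, ".conv2")]])
  h <- ad_adain(tape, h, layers[[paste0(prefix, ".ad2")]], labels)
  s <- if (!is.null(layers[[paste0(prefix, ".short")]]))
    ad_conv(tape, xn, layers[[paste0(prefix, ".short")]]) else xn
  ad_lrelu(tape, ad_add(tape, h, s))
}

# full generator graph; x may be an array or an existing tape node.
# returns list(out = output node, x = input node)
gen_forward <- function(g, x, ys, yt, tape) {
  cfg <- g$config
  ly <- g$layers
  L <- length(cfg$filters)
  if (!is.null(ys)) ys <- rbind(ys)
  if (!is.null(yt)) yt <- rbind(yt)
  src <- if (cfg$inject_source_labels) ys else NULL
  tgt <- if (cfg$inject_target_labels) yt else NULL
  xin <- if (is.environment(x)) x else ad_input(tape, x)
  x <- xin$val
  h <- ad_lrelu(tape, ad_conv(tape, xin, ly$stem))
  skips <- vector("list", L - 1)
  for (l in seq_len(L - 1)) {
    h <- res_fwd(tape, h, ly, paste0("enc", l), src)
    skips[[l]] <- h
    h <- ad_lrelu(tape, ad_conv(tape, h, ly[[paste0("down", l)]]))
  }
  h <- res_fwd(tape, h, ly, "bott", tgt)
  for (l in rev(seq_len(L - 1))) {
    h <- ad_upsample2(tape, h)
    h <- ad_lrelu(tape, ad_conv(tape, h, ly[[paste0("up", l)]]))
    h <- ad_concat(tape, h, skips[[l]])
    h <- res_fwd(tape, h, ly, paste0("dec", l), tgt)
  }
  h <- ad_upsample2(tape, h)
  h <- ad_lrelu(tape, ad_conv(tape, h, ly$final))
  o <- ad_conv(tape, h, ly$out)
  o <- ad_add(tape, o, ad_atanh_clip(tape, xin))
  list(out = ad_tanh(tape, o), x = xin)
}

#' @export
print.generator <- function(x, ...) {
  cat(sprintf("<generator> filters %s, base %d, inject src=%s tgt=%s, %d parameters%s\n",
              paste(x$config$filters, collapse = "-"), x$config$base_size,
              x$config$inject_source_labels, x$config$inject_target_labels,
              count_params(x$layers), if (!is.null(x$ema)) " (+EMA)" else ""))
  invisible(x)
}

#' Discriminator configuration
#'
#' A stack of strided residual blocks without normalization, global average
#' pooling and a single linear score output. The full-scale default is six
#' blocks with filters 64-128-256-512-512-512; the desk scale uses four.
#'
#' @param filters output channels of each residual block (one block per
#'   entry, each halving the resolution).
#' @param base_size input side length.
#' @return a `discriminator_config` list.
#' @export
discriminator_config <- function(filters = c(16, 32, 64, 64), base_size = 64) {
  structure(list(filters = filters, base_size = base_size),
            class = "discriminator_config")
}

#' Build the residual discriminator
#'
#' @param config a [discriminator_config()].
#' @param seed optional seed for weight initialization.
#' @return object of class `discriminator` with `$forward(x)` returning one
#'   raw (pre-sigmoid) score per sample and `$input_grad(x)` returning the
#'   gradient of each sample's score with respect to its input image.
#' @export
build_discriminator <- function(config = discriminator_config(), seed = NULL) {
  f <- config$filters
  B <- length(f)
  build <- function() {
    layers <- list(stem = new_conv_layer(1, f[1], stride = 2))
    cin <- f[1]
    for (i in seq_len(B)) {
      layers[[paste0("b", i, ".conv1")]] <- new_conv_layer(cin, f[i], stride = 2)
      layers[[paste0("b", i, ".conv2")]] <- new_conv_layer(f[i], f[i])
      layers[[paste0("b", i, ".short")]] <- new_conv_layer(cin, f[i], k = 1,
                                                           stride = 2, pad = 0)
      cin <- f[i]
    }
    layers$head <- new_dense_layer(f[B], 1)
    layers
  }
  layers <- if (is.null(seed)) build() else
    with_seed(substream_seed(seed, "disc_init"), build())
  d <- new.env(parent = emptyenv())
  d$layers <- layers
  d$config <- config
  class(d) <- "discriminator"
  d$forward_node <- function(x, tape = ad_tape()) disc_forward(d, x, tape)
  d$forward <- function(x)
    as.vector(disc_forward(d, as_batch(x), ad_tape(inference = TRUE))$out$val)
  d$input_grad <- function(x) {
    x <- as_batch(x)
    tape <- ad_tape()
    tape$no_param_grads <- TRUE  # probe: only the input gradient is wanted
    xin <- ad_input(tape, x)
    xin$want_grad <- TRUE
    r <- disc_forward(d, xin, tape)
    ad_backward(tape, r$out, matrix(1, dim(x)[4], 1))
    list(value = as.vector(r$out$val), grad = xin$grad)
  }
  d
}

disc_forward <- function(d, x, tape) {
  ly <- d$layers
  B <- length(d$config$filters)
  xin <- if (is.environment(x)) x else ad_input(tape, x)
  h <- ad_lrelu(tape, ad_conv(tape, xin, ly$stem))
  for (i in seq_len(B)) {
    a <- ad_lrelu(tape, ad_conv(tape, h, ly[[paste0("b", i, ".conv1")]]))
    a <- ad_conv(tape, a, ly[[paste0("b", i, ".conv2")]])
    s <- ad_conv(tape, h, ly[[paste0("b", i, ".short")]])
    h <- ad_lrelu(tape, ad_add(tape, a, s))
  }
  h <- ad_global_mean(tape, h)
  list(out = ad_dense(tape, h, ly$head), x = xin)
}

#' @export
print.discriminator <- function(x, ...) {
  cat(sprintf("<discriminator> %d residual blocks (%s), %d parameters\n",
              length(x$config$filters),
              paste(x$config$filters, collapse = "-"), count_params(x$layers)))
  invisible(x)
}

#' Build the auxiliary classifier
#'
#' Predicts `(te_scaled, tr_scaled, fs_logit)` from a single image. The
#' `small_cnn` backbone (four strided convolution blocks, global average
#' pooling, one hidden dense layer) is the CPU-scale default; heavier
#' pretrained backbones can be plugged in where an implementation is
#' available, but none ships with this package.
#'
#' @param backbone `"small_cnn"`.
#' @param input_size image side length the AC is trained at.
#' @param filters convolution widths of the four blocks.
#' @param seed optional seed for weight initialization.
#' @return object of class `aux_classifier` with `$predict(images)`
#'   returning an `N x 3` matrix; `$trained` is set by [pretrain_ac()].
#' @export
build_aux_classifier <- function(backbone = "small_cnn", input_size = 64,
                                 filters = c(8, 16, 32, 64), seed = NULL) {
  if (identical(backbone, "efficientnet_b3"))
    stop_arg("backbone 'efficientnet_b3' is not available in this build; ",
             "use 'small_cnn'")
  if (!identical(backbone, "small_cnn"))
    stop_arg("unknown backbone: ", backbone)
  build <- function() {
    layers <- list()
    cin <- 1
    for (i in seq_along(filters)) {
      layers[[paste0("conv", i)]] <- new_conv_layer(cin, filters[i], stride = 2)
      cin <- filters[i]
    }
    # the head sees the flattened coarse feature map, so the spatial layout
    # (fat rim at the border, body in the centre, pools in between) stays
    # available to the regression
    feat <- (input_size %/% 2^length(filters))^2 * cin
    layers$fc1 <- new_dense_layer(feat, 4 * cin)
    layers$head <- new_dense_layer(4 * cin, 3)
    layers
  }
  layers <- if (is.null(seed)) build() else
    with_seed(substream_seed(seed, "ac_init"), build())
  ac <- new.env(parent = emptyenv())
  ac$layers <- layers
  ac$backbone <- backbone
  ac$input_size <- input_size
  ac$config <- list(backbone = backbone, input_size = input_size,
                    filters = filters)
  ac$trained <- FALSE
  class(ac) <- "aux_classifier"
  ac$forward_node <- function(x, tape = ad_tape()) ac_forward(ac, x, tape)
  ac$predict <- function(images) {
    x <- as_batch(images)
    out <- matrix(0, dim(x)[4], 3)
    for (idx in chunk_indices(dim(x)[4], 64))
      out[idx, ] <- ac_forward(ac, x[, , , idx, drop = FALSE],
                               ad_tape(inference = TRUE))$out$val
    colnames(out) <- c("te_scaled", "tr_scaled", "fs_logit")
    out
  }
  ac
}

ac_forward <- function(ac, x, tape) {
  ly <- ac$layers
  xin <- if (is.environment(x)) x else ad_input(tape, x)
  h <- xin
  for (i in seq_len(sum(grepl("^conv", names(ly)))))
    h <- ad_lrelu(tape, ad_conv(tape, h, ly[[paste0("conv", i)]]))
  h <- ad_flatten(tape, h)
  h <- ad_lrelu(tape, ad_dense(tape, h, ly$fc1))
  list(out = ad_dense(tape, h, ly$head), x = xin)
}

#' @export
print.aux_classifier <- function(x, ...) {
  cat(sprintf("<aux_classifier> %s @%d, %d parameters, trained: %s\n",
              x$backbone, x$input_size, count_params(x$layers), x$trained))
  invisible(x)
}

as_batch <- function(x) {
  if (is.matrix(x)) array(x, c(nrow(x), ncol(x), 1, 1))
  else if (length(dim(x)) == 3) array(x, c(dim(x), 1))
  else x
}

chunk_indices <- function(n, size) {
  split(seq_len(n), ceiling(seq_len(n) / size))
}

check_scaled_label <- function(y, what) {
  y <- rbind(y)
  if (ncol(y) != 3 || any(!is.finite(y)) || any(y < 0) || any(y > 1))
    stop_arg(what, " must be scaled labels in [0,1]^3; use scale_labels()")
  y
}

#' Translate an image to a target contrast
#'
#' A single deterministic forward pass of the generator. When the generator
#' carries exponential-moving-average shadow weights (after training), those
#' are used, as at evaluation the EMA parameters are the model.
#'
#' @param generator a `generator`.
#' @param image matrix or `H x W x 1 x N` batch, preprocessed to `[-1, 1]`
#'   at the model size.
#' @param y_source,y_target scaled label vectors (length 3, or `N x 3`).
#' @param use_ema use EMA shadow weights when available.
#' @return translated image(s), same shape as the input.
#' @export
translate <- function(generator, image, y_source, y_target, use_ema = TRUE) {
  was_matrix <- is.matrix(image)
  x <- as_batch(image)
  n <- dim(x)[4]
  ys <- check_scaled_label(y_source, "y_source")
  yt <- check_scaled_label(y_target, "y_target")
  if (nrow(ys) == 1) ys <- ys[rep(1, n), , drop = FALSE]
  if (nrow(yt) == 1) yt <- yt[rep(1, n), , drop = FALSE]
  swap <- use_ema && !is.null(generator$ema)
  if (swap) {
    cur <- get_params(generator$layers)
    set_params(generator$layers, generator$ema)
    on.exit(set_params(generator$layers, cur))
  }
  out <- array(0, dim(x))
  for (idx in chunk_indices(n, 32)) {
    r <- gen_forward(generator, x[, , , idx, drop = FALSE],
                     ys[idx, , drop = FALSE], yt[idx, , drop = FALSE],
                     ad_tape(inference = TRUE))
    out[, , , idx] <- r$out$val
  }
  if (was_matrix) matrix(out, dim(x)[1], dim(x)[2]) else out
}

#' Synthesize a TE x TR contrast grid from one image
#'
#' Translates a single source image to every combination of the requested
#' echo and repetition times (at fixed fat saturation), ordered by
#' increasing TE and TR -- the contrast-interpolation view of a trained
#' model.
#'
#' @param generator a trained `generator`.
#' @param image source image matrix in `[-1, 1]`.
#' @param y_source scaled source label.
#' @param te_list,tr_list target times in ms.
#' @param fs target fat-saturation flag.
#' @return array `H x W x length(te_list) x length(tr_list)` with `te` and
#'   `tr` dimnames.
#' @export
contrast_grid <- function(generator, image, y_source, te_list, tr_list, fs = 0) {
  stopifnot(length(te_list) >= 1, length(tr_list) >= 1)
  te_list <- sort(te_list)
  tr_list <- sort(tr_list)
  grid <- expand.grid(te = te_list, tr = tr_list)
  yt <- scale_labels(grid$te, grid$tr, rep(fs, nrow(grid)))
  n <- nrow(grid)
  x <- array(rep(as.vector(image), n), c(nrow(image), ncol(image), 1, n))
  out <- translate(generator, x, rbind(y_source)[rep(1, n), ], yt)
  res <- array(out, c(nrow(image), ncol(image), length(te_list), length(tr_list)))
  dimnames(res) <- list(NULL, NULL, te = signif(te_list, 4), tr = signif(tr_list, 4))
  res
}

#' Number of trainable parameters of a network
#'
#' @param x a `generator`, `discriminator` or `aux_classifier`.
#' @return integer parameter count.
#' @export
n_parameters <- function(x) count_params(x$layers)

#' Save a model checkpoint
#'
#' Stores weights, configuration, EMA shadow weights and the label-scaling
#' constants in a single file, so translation from a checkpoint is
#' self-contained.
#'
#' @param x a `generator`, `discriminator` or `aux_classifier`.
#' @param path output file.
#' @export
save_checkpoint <- function(x, path) {
  obj <- list(class = class(x),
              config = x$config,
              params = get_params(x$layers),
              ema = x$ema,
              trained = x$trained,
              label_scaling = c(te_max = 50, tr_max = 5000),
              package_version = as.character(utils::packageVersion("mrcgan")))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint file.
#' @return the rebuilt model object.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  x <- switch(obj$class,
    generator = build_generator(obj$config),
    discriminator = build_discriminator(obj$config),
    aux_classifier = build_aux_classifier(obj$config$backbone,
                                          obj$config$input_size,
                                          obj$config$filters),
    stop_arg("unknown checkpoint class: ", obj$class))
  set_params(x$layers, obj$params)
  if (!is.null(obj$ema)) x$ema <- obj$ema
  if (!is.null(obj$trained)) x$trained <- obj$trained
  x
}
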