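#' Tissue parameter ranges for the knee-like phantom
#'
#' Per-class proton density (arbitrary units) and T1/T2 relaxation times (ms)
#' used by [generate_tissue_map()]. Values follow standard 1.5 T literature
#' ranges; within a structure the drawn value is modulated by a smooth spatial
#' field of at most +/- 5 percent.
#'
#' @return a named list of lists with elements `pd`, `t1`, `t2`, each a
#'   length-2 numeric range.
#' @export
tissue_classes <- function() {
  list(
    fat       = list(pd = c(0.80, 1.00), t1 = c(240, 300),   t2 = c(60, 80)),
    muscle    = list(pd = c(0.60, 0.80), t1 = c(800, 1100),  t2 = c(35, 50)),
    fluid     = list(pd = c(0.90, 1.00), t1 = c(2500, 3500), t2 = c(200, 400)),
    bone      = list(pd = c(0.05, 0.15), t1 = c(200, 400),   t2 = c(1, 10)),
    cartilage = list(pd = c(0.70, 0.90), t1 = c(900, 1200),  t2 = c(30, 45))
  )
}

#' Generate a random 2D tissue-parameter map
#'
#' Builds a phantom whose foreground is a union of `n_structures` possibly
#' overlapping ellipses with knee-like anatomy: a subcutaneous fat rim
#' always surrounds a muscle body, and bone, cartilage and synovial fluid
#' are present whenever the structure budget allows, as in a real knee
#' slice; any further structures are random interior ellipses of any
#' class. Each structure carries one tissue class with proton density, T1
#' and T2 drawn uniformly from that class's range (see [tissue_classes()]),
#' modulated by a smooth sinusoidal field of at most +/- 5 percent. Later
#' structures overwrite earlier ones where they overlap. Background pixels
#' have zero proton density.
#'
#' @param seed integer; identical seed, shape and structure count give
#'   bit-identical maps.
#' @param height,width image dimensions in pixels (at least 32).
#' @param n_structures number of ellipses (at least 1).
#' @return an object of class `tissue_map`: list with `height`, `width`,
#'   `class_map` (integer matrix, 0 = background, otherwise index into
#'   `names(tissue_classes())`), `pd_map`, `t1_map`, `t2_map`, `seed`.
#' @export
generate_tissue_map <- function(seed, height, width, n_structures = 6) {
  if (height < 32 || width < 32) stop_arg("height and width must be >= 32")
  if (n_structures < 1) stop_arg("n_structures must be >= 1")
  classes <- tissue_classes()
  cls <- matrix(0L, height, width)
  pd <- matrix(0, height, width)
  t1 <- matrix(0, height, width)
  t2 <- matrix(0, height, width)
  yy <- matrix(seq_len(height), height, width)
  xx <- matrix(seq_len(width), height, width, byrow = TRUE)
  # knee-like geometry: a subcutaneous fat rim always surrounds a muscle
  # body (structures 1 and 2: a large fat ellipse overwritten by a slightly
  # smaller concentric muscle ellipse), and bone, cartilage and fluid are
  # present whenever the structure budget allows, as in any real knee slice
  # (femur/tibia, articular cartilage, synovial fluid). This keeps every
  # acquisition parameter identifiable from every image: the fat rim reads
  # out fat saturation and T2-weighting, the long-T1 fluid pool reads out
  # the repetition time. Remaining structures are random interior ellipses.
  fixed <- match(c("fat", "muscle", "bone", "cartilage", "fluid"),
                 names(classes))
  with_seed(substream_seed(seed, "tissue_map"), {
    rim_ay <- runif(1, 0.44, 0.48)
    rim_ax <- runif(1, 0.44, 0.48)
    rim_cy <- runif(1, 0.48, 0.52)
    rim_cx <- runif(1, 0.48, 0.52)
    for (s in seq_len(n_structures)) {
      body <- s <= 2 && n_structures >= 2
      ci <- if (n_structures >= 2 && s <= length(fixed)) fixed[s]
            else sample.int(length(classes), 1L)
      p <- classes[[ci]]
      if (body) {
        shrink <- if (s == 1) 1 else runif(1, 0.82, 0.90)
        cy <- rim_cy * height
        cx <- rim_cx * width
        ay <- rim_ay * shrink * height
        ax <- rim_ax * shrink * width
        th <- 0
      } else {
        cy <- runif(1, 0.3, 0.7) * height
        cx <- runif(1, 0.3, 0.7) * width
        ay <- runif(1, 0.06, 0.20) * height
        ax <- runif(1, 0.06, 0.20) * width
        th <- runif(1, 0, pi)
      }
      dy <- (yy - cy) / ay
      dx <- (xx - cx) / ax
      u <- cos(th) * dy + sin(th) * dx
      v <- -sin(th) * dy + cos(th) * dx
      inside <- (u^2 + v^2) <= 1
      # smooth <=5% modulation, shared by pd/t1/t2 so t1 >= t2 is preserved
      amp <- runif(1, 0, 0.05)
      f <- 1 + amp * sin(2 * pi * (runif(1, 0.3, 1.2) * yy / height + runif(1))) *
        sin(2 * pi * (runif(1, 0.3, 1.2) * xx / width + runif(1)))
      cls[inside] <- ci
      pd[inside] <- (runif(1, p$pd[1], p$pd[2]) * f)[inside]
      t1[inside] <- (runif(1, p$t1[1], p$t1[2]) * f)[inside]
      t2[inside] <- (runif(1, p$t2[1], p$t2[2]) * f)[inside]
    }
  })
  structure(list(height = height, width = width, class_map = cls,
                 pd_map = pd, t1_map = t1, t2_map = t2, seed = seed),
            class = "tissue_map")
}

#' @export
print.tissue_map <- function(x, ...) {
  fg <- mean(x$class_map > 0)
  cat(sprintf("<tissue_map> %d x %d, %.0f%% foreground, classes: %s\n",
              x$height, x$width, 100 * fg,
              paste(names(tissue_classes())[sort(unique(x$class_map[x$class_map > 0]))],
                    collapse = ", ")))
  invisible(x)
}

#' Spin-echo signal equation
#'
#' Classical spin-echo magnitude signal
#' \deqn{S = PD \cdot (1 - e^{-TR/T1}) \cdot e^{-TE/T2},}
#' the analytic contrast model of the phantom: signal decreases with TE
#' (T2-weighting) and increases with TR (T1 recovery). Vectorized; pixels
#' with zero proton density return exactly zero.
#'
#' @param pd proton density (>= 0).
#' @param t1_ms,t2_ms relaxation times in ms (> 0 wherever `pd > 0`).
#' @param te_ms,tr_ms echo and repetition time in ms (> 0).
#' @return signal intensity, same shape as `pd`.
#' @export
spin_echo_signal <- function(pd, t1_ms, t2_ms, te_ms, tr_ms) {
  if (any(pd < 0) || any(te_ms <= 0) || any(tr_ms <= 0))
    stop_arg("pd must be >= 0 and te_ms, tr_ms > 0")
  if (any(t1_ms[pd > 0] <= 0) || any(t2_ms[pd > 0] <= 0))
    stop_arg("t1_ms and t2_ms must be > 0 wherever pd > 0")
  s <- pd
  fg <- pd > 0
  s[fg] <- pd[fg] * (1 - exp(-tr_ms / t1_ms[fg])) * exp(-te_ms / t2_ms[fg])
  s
}

#' Construct an acquisition label (TE, TR, fat saturation)
#'
#' @param te_ms echo time in ms, in (0, 50].
#' @param tr_ms repetition time in ms, in (0, 5000].
#' @param fs fat-saturation flag, 0 or 1.
#' @param te_max,tr_max scaling denominators (the dataset filter bounds).
#' @return object of class `acq_label` with the raw and `[0,1]`-scaled values.
#' @export
acquisition_label <- function(te_ms, tr_ms, fs, te_max = 50, tr_max = 5000) {
  if (te_ms <= 0 || te_ms > te_max) stop_arg("te_ms must be in (0, ", te_max, "]")
  if (tr_ms <= 0 || tr_ms > tr_max) stop_arg("tr_ms must be in (0, ", tr_max, "]")
  if (!fs %in% c(0, 1)) stop_arg("fs must be 0 or 1")
  structure(list(te_ms = te_ms, tr_ms = tr_ms, fs = as.numeric(fs),
                 te_scaled = te_ms / te_max, tr_scaled = tr_ms / tr_max,
                 te_max = te_max, tr_max = tr_max),
            class = "acq_label")
}

#' @export
print.acq_label <- function(x, ...) {
  cat(sprintf("<acq_label> TE %.1f ms, TR %.0f ms, FS %d\n",
              x$te_ms, x$tr_ms, as.integer(x$fs)))
  invisible(x)
}

#' Default TE/TR/FS sampler emulating a clinical knee protocol mix
#'
#' A mixture of a non-fat-saturated cluster (TE 25-35 ms, TR 2000-3500 ms),
#' a fat-saturated cluster (TE 30-45 ms, TR 2500-4500 ms) and a small uniform
#' background mass over the full admissible box (TE (0,50], TR (0,5000],
#' random FS), mimicking how acquisition parameters cluster by sequence type
#' in clinical archives.
#'
#' @param w_nonfs,w_fs,w_uniform mixture weights (normalized internally).
#' @return a `label_sampler` object usable by [sample_acquisition_labels()].
#' @export
default_label_sampler <- function(w_nonfs = 0.45, w_fs = 0.45, w_uniform = 0.10) {
  w <- c(w_nonfs, w_fs, w_uniform)
  structure(list(
    components = list(
      list(w = w[1], te = c(25, 35), tr = c(2000, 3500), fs = 0),
      list(w = w[2], te = c(30, 45), tr = c(2500, 4500), fs = 1),
      list(w = w[3], te = c(1, 50), tr = c(100, 5000), fs = NA)
    )
  ), class = "label_sampler")
}

#' Draw acquisition labels from a sampler
#'
#' @param n number of labels.
#' @param seed integer seed.
#' @param sampler a `label_sampler`; see [default_label_sampler()].
#' @param fs if 0 or 1, condition the draw on that fat-saturation value
#'   (components with the other flag are excluded; the uniform component
#'   keeps its mass and emits the requested flag).
#' @return a data.frame with columns `te_ms`, `tr_ms`, `fs`.
#' @export
sample_acquisition_labels <- function(n, seed, sampler = default_label_sampler(),
                                      fs = NA) {
  comps <- sampler$components
  if (!is.na(fs))
    comps <- Filter(function(cm) is.na(cm$fs) || cm$fs == fs, comps)
  w <- vapply(comps, `[[`, numeric(1), "w")
  w <- w / sum(w)
  with_seed(substream_seed(seed, "labels"), {
    idx <- sample.int(length(comps), n, replace = TRUE, prob = w)
    te <- tr <- fsv <- numeric(n)
    for (i in seq_len(n)) {
      cm <- comps[[idx[i]]]
      te[i] <- runif(1, cm$te[1], cm$te[2])
      tr[i] <- runif(1, cm$tr[1], cm$tr[2])
      fsv[i] <- if (!is.na(fs)) fs else if (is.na(cm$fs)) rbinom(1, 1, 0.5) else cm$fs
    }
    data.frame(te_ms = te, tr_ms = tr, fs = fsv)
  })
}

#' Render a tissue map under an acquisition label
#'
#' Applies [spin_echo_signal()] per pixel; with fat saturation on, fat-class
#' pixels are multiplied by `fs_suppression` before noise. Zero-mean Gaussian
#' noise with standard deviation `noise_sd` (in units of the signal dynamic
#' range `[0, 1]`) is added, the image is clipped to `[0, 1]` (1 is the
#' phantom's proton-density ceiling, so the scale is absolute across images)
#' and mapped linearly to `[-1, 1]`.
#'
#' @param map a `tissue_map`.
#' @param label an `acq_label`.
#' @param noise_sd Gaussian noise sd (>= 0), default 0.01.
#' @param seed integer seed for the noise draw.
#' @param fs_suppression multiplicative fat suppression factor, default 0.05.
#' @return an `height x width` matrix in `[-1, 1]`.
#' @export
render_image <- function(map, label, noise_sd = 0.01, seed = 0,
                         fs_suppression = 0.05) {
  stopifnot(inherits(map, "tissue_map"), inherits(label, "acq_label"))
  if (noise_sd < 0) stop_arg("noise_sd must be >= 0")
  s <- spin_echo_signal(map$pd_map, map$t1_map, map$t2_map,
                        label$te_ms, label$tr_ms)
  if (label$fs == 1) {
    fat <- map$class_map == match("fat", names(tissue_classes()))
    s[fat] <- s[fat] * fs_suppression
  }
  if (noise_sd > 0)
    s <- s + with_seed(substream_seed(seed, "render_noise"),
                       matrix(rnorm(length(s), 0, noise_sd), nrow(s), ncol(s)))
  s <- pmin(pmax(s, 0), 1)
  2 * s - 1
}

#' Generate a synthetic paired/unpaired MR dataset
#'
#' A "subject" contributes `slices_per_subject` tissue maps; each map is
#' rendered under one or two acquisition labels. A fraction `pair_fraction`
#' of all samples belong to two-element pairs sharing a map: the source is
#' always non-fat-saturated, the target is fat-saturated with probability
#' `pair_target_fs_prob` (otherwise a second non-FS contrast). Remaining
#' samples are unpaired single renders with sampler-drawn labels.
#'
#' @param seed integer seed controlling geometry, labels and noise.
#' @param n_subjects,slices_per_subject dataset size.
#' @param pair_fraction fraction of samples that are members of pairs, in
#'   `[0, 1]`.
#' @param label_sampler a `label_sampler`.
#' @param height,width,n_structures phantom geometry.
#' @param noise_sd render noise sd.
#' @param pair_target_fs_prob probability that a pair's target is
#'   fat-saturated.
#' @param keep_maps keep the tissue maps (needed for region-wise evaluation).
#' @return an object of class `mr_dataset`: list with `images` (array
#'   `H x W x 1 x N` in `[-1,1]`), `meta` (data.frame with `sample_id`,
#'   `subject_id`, `slice_index`, `map_id`, `te_ms`, `tr_ms`, `fs`,
#'   `pair_id`, `role`), `maps`, `height`, `width`, `seed`.
#' @export
make_synthetic_dataset <- function(seed, n_subjects, slices_per_subject = 1,
                                   pair_fraction = 1,
                                   label_sampler = default_label_sampler(),
                                   height = 64, width = 64, n_structures = 6,
                                   noise_sd = 0.01, pair_target_fs_prob = 0.5,
                                   keep_maps = TRUE) {
  if (pair_fraction < 0 || pair_fraction > 1)
    stop_arg("pair_fraction must be in [0, 1]")
  n_slices <- n_subjects * slices_per_subject
  # a paired slice yields 2 samples: q paired slices out of m give a paired
  # *sample* share of 2q/(m+q); invert for the slice count
  n_paired <- round(n_slices * pair_fraction / (2 - pair_fraction))
  paired <- rep(FALSE, n_slices)
  if (n_paired > 0)
    paired[with_seed(substream_seed(seed, "pair_assign"),
                     sample.int(n_slices, n_paired))] <- TRUE

  n_samples <- n_paired * 2L + (n_slices - n_paired)
  images <- array(0, c(height, width, 1, n_samples))
  meta <- data.frame(sample_id = seq_len(n_samples), subject_id = 0L,
                     slice_index = 0L, map_id = 0L, te_ms = 0, tr_ms = 0,
                     fs = 0, pair_id = NA_integer_,
                     role = NA_character_, stringsAsFactors = FALSE)
  maps <- vector("list", n_slices)

  src_lab <- sample_acquisition_labels(n_slices, substream_seed(seed, "src"),
                                       label_sampler, fs = 0)
  tgt_fs <- with_seed(substream_seed(seed, "tgt_fs"),
                      rbinom(n_slices, 1, pair_target_fs_prob))
  tgt_fs_lab <- sample_acquisition_labels(n_slices, substream_seed(seed, "tgt1"),
                                          label_sampler, fs = 1)
  tgt_nonfs_lab <- sample_acquisition_labels(n_slices, substream_seed(seed, "tgt0"),
                                             label_sampler, fs = 0)
  unp_lab <- sample_acquisition_labels(n_slices, substream_seed(seed, "unp"),
                                       label_sampler)

  k <- 0L
  pair_id <- 0L
  for (i in seq_len(n_slices)) {
    subj <- (i - 1L) %/% slices_per_subject + 1L
    sl <- (i - 1L) %% slices_per_subject
    map <- generate_tissue_map(substream_seed(seed, paste0("map", i)),
                               height, width, n_structures)
    if (keep_maps) maps[[i]] <- map
    add_sample <- function(lab_row, role, pid) {
      k <<- k + 1L
      lab <- acquisition_label(lab_row$te_ms, lab_row$tr_ms, lab_row$fs)
      images[, , 1, k] <<- render_image(map, lab, noise_sd,
                                        seed = substream_seed(seed, paste0("n", k)))
      meta$subject_id[k] <<- subj
      meta$slice_index[k] <<- sl
      meta$map_id[k] <<- i
      meta$te_ms[k] <<- lab$te_ms
      meta$tr_ms[k] <<- lab$tr_ms
      meta$fs[k] <<- lab$fs
      meta$pair_id[k] <<- pid
      meta$role[k] <<- role
    }
    if (paired[i]) {
      pair_id <- pair_id + 1L
      tgt <- if (tgt_fs[i] == 1) tgt_fs_lab[i, ] else tgt_nonfs_lab[i, ]
      add_sample(src_lab[i, ], "source", pair_id)
      add_sample(tgt, "target", pair_id)
    } else {
      add_sample(unp_lab[i, ], "unpaired", NA_integer_)
    }
  }
  structure(list(images = images, meta = meta,
                 maps = if (keep_maps) maps else NULL,
                 height = height, width = width, noise_sd = noise_sd,
                 label_sampler = label_sampler, seed = seed),
            class = "mr_dataset")
}

#' @export
print.mr_dataset <- function(x, ...) {
  np <- sum(!is.na(x$meta$pair_id))
  cat(sprintf(
    "<mr_dataset> %d samples (%d paired, %d unpaired), %d x %d, %d FS\n",
    nrow(x$meta), np, nrow(x$meta) - np, x$height, x$width, sum(x$meta$fs == 1)))
  invisible(x)
}

#' Mean intensity over the pixels of one tissue class
#'
#' Convenience accessor used to verify contrast behaviour (e.g. that muscle
#' signal decreases with TE) on rendered or synthesized images.
#'
#' @param image a matrix (or `H x W x 1 x 1` array).
#' @param map the `tissue_map` the image derives from.
#' @param class_name one of `names(tissue_classes())`.
#' @return mean intensity, or `NA` if the class is absent.
#' @export
region_mean <- function(image, map, class_name) {
  ci <- match(class_name, names(tissue_classes()))
  m <- map$class_map == ci
  if (!any(m)) return(NA_real_)
  img <- if (is.matrix(image)) image else array(image, dim(map$class_map))
  mean(img[m])
}
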