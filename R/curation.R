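#' Filter metadata records on acquisition-parameter and scanner criteria
#'
#' Keeps records with `tr_ms <= tr_max`, `te_ms <= te_max` (bounds inclusive:
#' records *over* the limit are excluded) and, unless a `"*"` wildcard is
#' given, a matching field strength and manufacturer. Row order is preserved.
#'
#' @param records data.frame of series records (columns `te_ms`, `tr_ms`,
#'   `field_strength`, `manufacturer`, ... see [dataset_records()]).
#' @param tr_max,te_max upper limits in ms (defaults 5000 and 50).
#' @param field_strength tesla value to keep, or `"*"` to skip the filter.
#' @param manufacturer manufacturer string to keep, or `"*"`.
#' @return the retained subset of `records`.
#' @export
filter_records <- function(records, tr_max = 5000, te_max = 50,
                           field_strength = "*", manufacturer = "*") {
  if (tr_max <= 0 || te_max <= 0) stop_arg("tr_max and te_max must be > 0")
  keep <- records$tr_ms <= tr_max & records$te_ms <= te_max
  if (!identical(field_strength, "*"))
    keep <- keep & abs(records$field_strength - as.numeric(field_strength)) < 1e-6
  if (!identical(manufacturer, "*"))
    keep <- keep & records$manufacturer == manufacturer
  records[keep, , drop = FALSE]
}

#' Select the central slices of one series
#'
#' Returns the `k` slices whose indices are centered on `floor(n/2)` where
#' `n` is the series' slice count: the window is
#' `[floor(n/2) - floor(k/2), floor(n/2) - floor(k/2) + k)`. If the series
#' has at most `k` slices, all are returned. Output is ordered by
#' `slice_index`.
#'
#' @param records data.frame of records sharing one `series_uid`.
#' @param k number of central slices to keep.
#' @return the selected subset, sorted by `slice_index`.
#' @export
select_central_slices <- function(records, k) {
  if (k < 1) stop_arg("k must be >= 1")
  if (length(unique(records$series_uid)) > 1)
    stop_arg("records must share a single series_uid")
  n <- records$n_slices[1]
  records <- records[order(records$slice_index), , drop = FALSE]
  if (n <= k) return(records)
  lo <- n %/% 2L - k %/% 2L
  records[records$slice_index >= lo & records$slice_index < lo + k, , drop = FALSE]
}

# greedy tolerance clustering of scalar values (sorted, new cluster when the
# gap to the cluster representative exceeds tol); returns integer cluster ids
.tol_cluster <- function(x, tol) {
  o <- order(x)
  id <- integer(length(x))
  cur <- 0L
  rep_val <- -Inf
  for (i in o) {
    if (cur == 0L || abs(x[i] - rep_val) > tol) {
      cur <- cur + 1L
      rep_val <- x[i]
    }
    id[i] <- cur
  }
  id
}

#' Pair records that share the five pairing attributes
#'
#' Groups records by patient ID, study UID, image orientation (element-wise
#' within `orientation_tol`), slice location (within `slice_location_tol`)
#' and slice thickness, then emits one pair per ordered combination of a
#' non-fat-saturated source and any other record from a different series
#' within the group. Records without a partner simply yield no pair and
#' remain available as unpaired data.
#'
#' @param records data.frame of (already filtered) records. The image
#'   orientation is a character column of 6 numbers separated by `\\`.
#' @param slice_location_tol matching tolerance in mm (default 0.5).
#' @param orientation_tol element-wise orientation tolerance (default 1e-3).
#' @return data.frame with one row per pair: `pair_key`, `source_row`,
#'   `target_row` (row indices into `records`), source and target series.
#' @export
pair_images <- function(records, slice_location_tol = 0.5,
                        orientation_tol = 1e-3) {
  n <- nrow(records)
  if (n == 0)
    return(data.frame(pair_key = character(), source_row = integer(),
                      target_row = integer(), stringsAsFactors = FALSE))
  ori <- do.call(rbind, lapply(strsplit(records$image_orientation, "\\\\"),
                               as.numeric))
  # cluster orientations by first-seen representative within tol
  ori_id <- integer(n)
  reps <- list()
  for (i in order(records$patient_id, records$study_uid)) {
    hit <- 0L
    for (j in seq_along(reps))
      if (all(abs(ori[i, ] - reps[[j]]) <= orientation_tol)) { hit <- j; break }
    if (hit == 0L) { reps[[length(reps) + 1L]] <- ori[i, ]; hit <- length(reps) }
    ori_id[i] <- hit
  }
  loc_id <- integer(n)
  base <- interaction(records$patient_id, records$study_uid, ori_id,
                      records$slice_thickness, drop = TRUE)
  for (g in levels(base)) {
    idx <- which(base == g)
    loc_id[idx] <- .tol_cluster(records$slice_location[idx], slice_location_tol)
  }
  grp <- interaction(base, loc_id, drop = TRUE)

  out <- list()
  for (g in levels(grp)) {
    idx <- sort(which(grp == g))
    src <- idx[records$fs[idx] == 0]
    for (s in src) for (t in idx) {
      if (records$series_uid[t] == records$series_uid[s]) next
      out[[length(out) + 1L]] <- data.frame(
        pair_key = paste0(g, ":", s, ">", t),
        source_row = s, target_row = t, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(pair_key = character(), source_row = integer(),
                      target_row = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Resize with bilinear interpolation and rescale intensities to `[-1, 1]`
#'
#' Resizing uses half-pixel-centre bilinear interpolation; the intensity
#' rescale then maps the image minimum to -1 and maximum to +1, so the
#' output always attains the full range and preprocessing an
#' already-preprocessed image is the identity. Constant images (no
#' contrast) map to -1 everywhere.
#'
#' @param image numeric matrix.
#' @param out_size output side length in pixels.
#' @return an `out_size x out_size` matrix in `[-1, 1]`.
#' @export
preprocess <- function(image, out_size) {
  stopifnot(is.matrix(image), nrow(image) > 0, ncol(image) > 0)
  img <- image
  if (nrow(img) != out_size || ncol(img) != out_size) {
    x <- array(img, c(nrow(img), ncol(img), 1, 1))
    img <- matrix(cpp_bilinear_resize(x, out_size, out_size), out_size, out_size)
  }
  rng <- range(img)
  if (rng[2] > rng[1]) 2 * (img - rng[1]) / (rng[2] - rng[1]) - 1
  else matrix(-1, out_size, out_size)
}

#' Random shift-and-zoom augmentation
#'
#' Applies a random translation of up to `max_shift` times the image side and
#' a random zoom drawn from `zoom_range`, with reflection padding and
#' bilinear resampling. Deterministic given the seed.
#'
#' @param image numeric matrix.
#' @param seed integer seed.
#' @param max_shift maximum shift as a fraction of the side, in `[0, 0.5)`.
#' @param zoom_range length-2 interval inside `(0.5, 2)`.
#' @return augmented matrix of the same size.
#' @export
augment <- function(image, seed, max_shift = 0.05, zoom_range = c(0.9, 1.1)) {
  stopifnot(is.matrix(image))
  if (max_shift < 0 || max_shift >= 0.5) stop_arg("max_shift must be in [0, 0.5)")
  if (zoom_range[1] <= 0.5 || zoom_range[2] >= 2 || zoom_range[1] > zoom_range[2])
    stop_arg("zoom_range must be an interval inside (0.5, 2)")
  prm <- with_seed(substream_seed(seed, "augment"), {
    list(dh = runif(1, -max_shift, max_shift) * nrow(image),
         dw = runif(1, -max_shift, max_shift) * ncol(image),
         z = runif(1, zoom_range[1], zoom_range[2]))
  })
  x <- array(image, c(nrow(image), ncol(image), 1, 1))
  matrix(cpp_affine_sample(x, prm$dh, prm$dw, prm$z), nrow(image), ncol(image))
}

# batch augmentation used in the training loops; one transform per *pair*
# (source and target must stay registered), images is H x W x 1 x N,
# group is an integer vector assigning samples to shared transforms
augment_batch <- function(images, seed, group = seq_len(dim(images)[4]),
                          max_shift = 0.05, zoom_range = c(0.9, 1.1)) {
  ng <- max(group)
  prm <- with_seed(substream_seed(seed, "augment_batch"), {
    list(dh = runif(ng, -max_shift, max_shift) * dim(images)[1],
         dw = runif(ng, -max_shift, max_shift) * dim(images)[2],
         z = runif(ng, zoom_range[1], zoom_range[2]))
  })
  cpp_affine_sample(images, prm$dh[group], prm$dw[group], prm$z[group])
}

#' Express a synthetic dataset as DICOM-style series records
#'
#' Maps the synthetic manifest onto the metadata schema the curation rules
#' operate on (one record per image): subjects become patient IDs, each
#' rendered contrast of a slice becomes its own series, and the slice's map
#' index becomes the slice location so that only same-map renders can pair.
#'
#' @param ds an `mr_dataset`.
#' @return data.frame of series records.
#' @export
dataset_records <- function(ds) {
  m <- ds$meta
  data.frame(
    patient_id = sprintf("P%04d", m$subject_id),
    study_uid = sprintf("S%04d.1", m$subject_id),
    series_uid = sprintf("S%04d.%d.%d", m$subject_id, m$map_id, m$sample_id),
    image_orientation = "1\\0\\0\\0\\1\\0",
    slice_location = m$map_id * 10,
    slice_thickness = 3,
    te_ms = m$te_ms, tr_ms = m$tr_ms, fs = m$fs,
    field_strength = 1.5, manufacturer = "SIEMENS",
    n_slices = 1L, slice_index = 0L,
    sample_id = m$sample_id, pair_id = m$pair_id,
    stringsAsFactors = FALSE)
}

#' Materialize image pairs from a synthetic dataset
#'
#' @param ds an `mr_dataset`.
#' @param which optional subset of pair ids.
#' @return list of `image_pair` objects: each holds `source` and `target`
#'   (image matrix + `acq_label`), the `pair_key` and the map id.
#' @export
dataset_pairs <- function(ds, which = NULL) {
  m <- ds$meta
  pids <- sort(unique(m$pair_id[!is.na(m$pair_id)]))
  if (!is.null(which)) pids <- intersect(pids, which)
  lapply(pids, function(p) {
    si <- which(m$pair_id == p & m$role == "source")
    ti <- which(m$pair_id == p & m$role == "target")
    structure(list(
      source = list(image = ds$images[, , 1, si],
                    label = acquisition_label(m$te_ms[si], m$tr_ms[si], m$fs[si])),
      target = list(image = ds$images[, , 1, ti],
                    label = acquisition_label(m$te_ms[ti], m$tr_ms[ti], m$fs[ti])),
      pair_key = sprintf("pair%05d", p), map_id = m$map_id[si]),
      class = "image_pair")
  })
}
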