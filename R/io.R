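# NPY v1.0 read/write for 2D float64 arrays (column-major on disk, matching
# the package's image layout). Only the subset the package needs.

npy_write <- function(mat, path) {
  dims <- paste(dim(mat), collapse = ", ")
  header <- sprintf("{'descr': '<f8', 'fortran_order': True, 'shape': (%s), }",
                    dims)
  pad <- (64 - (10 + nchar(header) + 1) %% 64) %% 64
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, utf8ToInt("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.vector(mat), con, size = 8, endian = "little")
  invisible(path)
}

npy_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  if (!identical(as.integer(magic[1]), 0x93L))
    stop_arg("not an NPY file: ", path)
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  shape <- regmatches(header, regexpr("\\(([0-9, ]*)\\)", header))
  dims <- as.integer(strsplit(gsub("[() ]", "", shape), ",")[[1]])
  fortran <- grepl("'fortran_order': True", header, fixed = TRUE)
  x <- readBin(con, "double", prod(dims), size = 8, endian = "little")
  m <- if (fortran) array(x, dims) else aperm(array(x, rev(dims)))
  m
}

#' Write a synthetic dataset to disk
#'
#' One directory per dataset: an `images/` folder with one file per sample
#' and a `manifest.csv` with columns `subject_id`, `slice_index`, `te_ms`,
#' `tr_ms`, `fs`, `pair_id`, `file`. The `npy` format stores lossless
#' float64 arrays; `png` stores an 8-bit preview rescaled to `[0, 1]`.
#'
#' @param ds an `mr_dataset`.
#' @param dir output directory (created).
#' @param format `"npy"` (default, lossless) or `"png"`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, format = c("npy", "png")) {
  format <- match.arg(format)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  m <- ds$meta
  files <- sprintf("images/sample%05d.%s", m$sample_id, format)
  for (i in seq_len(nrow(m))) {
    img <- ds$images[, , 1, i]
    if (format == "npy") npy_write(img, file.path(dir, files[i]))
    else png::writePNG((img + 1) / 2, file.path(dir, files[i]))
  }
  manifest <- data.frame(subject_id = m$subject_id, slice_index = m$slice_index,
                         map_id = m$map_id, te_ms = m$te_ms, tr_ms = m$tr_ms,
                         fs = m$fs, pair_id = m$pair_id, role = m$role,
                         file = files)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return an `mr_dataset` (without tissue maps).
#' @export
read_dataset <- function(dir) {
  m <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  first <- file.path(dir, m$file[1])
  img1 <- if (grepl("\\.npy$", first)) npy_read(first)
          else png::readPNG(first) * 2 - 1
  images <- array(0, c(nrow(img1), ncol(img1), 1, nrow(m)))
  for (i in seq_len(nrow(m))) {
    f <- file.path(dir, m$file[i])
    images[, , 1, i] <- if (grepl("\\.npy$", f)) npy_read(f)
                        else png::readPNG(f) * 2 - 1
  }
  meta <- data.frame(sample_id = seq_len(nrow(m)), subject_id = m$subject_id,
                     slice_index = m$slice_index,
                     map_id = m$map_id %||% seq_len(nrow(m)),
                     te_ms = m$te_ms, tr_ms = m$tr_ms, fs = m$fs,
                     pair_id = m$pair_id, role = m$role,
                     stringsAsFactors = FALSE)
  structure(list(images = images, meta = meta, maps = NULL,
                 height = nrow(img1), width = ncol(img1),
                 label_sampler = default_label_sampler(), seed = NA),
            class = "mr_dataset")
}
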