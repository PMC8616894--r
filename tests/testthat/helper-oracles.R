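# Independent brute-force oracles and shared fixtures for the test suite.
# Oracles are deliberately written as plain scalar loops, independent of the
# package's vectorized/C++ code paths.

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# windowed SSIM by explicit window loops (valid region, Gaussian weights)
brute_ssim_windowed <- function(x, y, win = 11, sigma = 1.5, L = 2) {
  k1 <- exp(-((seq_len(win)) - (win + 1) / 2)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  H <- nrow(x); W <- ncol(x)
  vals <- c()
  for (i in 1:(H - win + 1)) for (j in 1:(W - win + 1)) {
    px <- x[i:(i + win - 1), j:(j + win - 1)]
    py <- y[i:(i + win - 1), j:(j + win - 1)]
    mx <- sum(K * px); my <- sum(K * py)
    vx <- sum(K * px^2) - mx^2
    vy <- sum(K * py^2) - my^2
    cxy <- sum(K * px * py) - mx * my
    vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  mean(vals)
}

brute_ssim_global <- function(x, y, L = 2) {
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

brute_nmse <- function(x, y) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + (x[i] - y[i])^2
    den <- den + x[i]^2
  }
  num / den
}

brute_psnr <- function(x, y) {
  mse <- 0
  for (i in seq_along(x)) mse <- mse + (x[i] - y[i])^2
  mse <- mse / length(x)
  rng <- max(c(x, y)) - min(c(x, y))
  10 * log10(rng^2 / mse)
}

# noise-free spin-echo render by scalar loops (mirrors the documented model:
# per-pixel closed form, FS fat suppression, clip to [0,1], map to [-1,1])
brute_render <- function(map, te, tr, fs, fs_suppression = 0.05) {
  out <- matrix(0, map$height, map$width)
  fat_class <- match("fat", names(tissue_classes()))
  for (i in seq_len(map$height)) for (j in seq_len(map$width)) {
    pd <- map$pd_map[i, j]
    s <- 0
    if (pd > 0) {
      s <- pd * (1 - exp(-tr / map$t1_map[i, j])) * exp(-te / map$t2_map[i, j])
      if (fs == 1 && map$class_map[i, j] == fat_class) s <- s * fs_suppression
    }
    s <- min(max(s, 0), 1)
    out[i, j] <- 2 * s - 1
  }
  out
}

# small shared datasets, built once per test run
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_synthetic_dataset(seed = 42, n_subjects = 12,
                                       slices_per_subject = 2,
                                       pair_fraction = 1, noise_sd = 0.01)
    cache
  }
})

# 200 metadata records with known composition; expectations are frozen
# hand counts derived from the construction below
make_records_fixture <- function() {
  rec <- function(pid, study, series, ori, loc, thick, te, tr, fs,
                  field = 1.5, manu = "SIEMENS", n_slices = 1, idx = 0) {
    data.frame(patient_id = pid, study_uid = study, series_uid = series,
               image_orientation = ori, slice_location = loc,
               slice_thickness = thick, te_ms = te, tr_ms = tr, fs = fs,
               field_strength = field, manufacturer = manu,
               n_slices = n_slices, slice_index = idx,
               stringsAsFactors = FALSE)
  }
  ax <- "1\\0\\0\\0\\1\\0"
  rows <- list()
  # 20 two-record groups: one non-FS + one FS sharing the five attributes
  for (g in 1:20) {
    pid <- sprintf("PA%02d", g)
    rows[[length(rows) + 1]] <- rec(pid, paste0(pid, ".st"), paste0(pid, ".s1"),
                                    ax, g * 10, 3, 30, 3000, 0)
    rows[[length(rows) + 1]] <- rec(pid, paste0(pid, ".st"), paste0(pid, ".s2"),
                                    ax, g * 10 + 0.2, 3, 40, 4000, 1)
  }
  # 5 three-record groups: one non-FS source + two targets -> 2 pairs each
  for (g in 1:5) {
    pid <- sprintf("PB%02d", g)
    rows[[length(rows) + 1]] <- rec(pid, paste0(pid, ".st"), paste0(pid, ".s1"),
                                    ax, 5, 3, 28, 2800, 0)
    rows[[length(rows) + 1]] <- rec(pid, paste0(pid, ".st"), paste0(pid, ".s2"),
                                    ax, 5.1, 3, 35, 3500, 1)
    rows[[length(rows) + 1]] <- rec(pid, paste0(pid, ".st"), paste0(pid, ".s3"),
                                    ax, 4.9, 3, 45, 4200, 1)
  }
  # 10 lone records with unique locations: no partner, no pair
  for (g in 1:10)
    rows[[length(rows) + 1]] <- rec(sprintf("PC%02d", g), "c.st",
                                    sprintf("c.s%d", g), ax, 1000 + g * 50, 3,
                                    30, 3000, g %% 2)
  # one 30-slice series (distinct locations, same series: never pairs)
  for (s in 0:29)
    rows[[length(rows) + 1]] <- rec("PD01", "d.st", "d.s1", ax, 2000 + s * 3, 3,
                                    32, 3200, 0, n_slices = 30, idx = s)
  # 25 fillers, unique patients
  for (g in 1:25)
    rows[[length(rows) + 1]] <- rec(sprintf("PE%02d", g), "e.st",
                                    sprintf("e.s%d", g), ax, 3000 + g * 40, 3,
                                    25, 2500, 0)
  # 45 records excluded by the TR filter, 35 by the TE filter
  for (g in 1:45)
    rows[[length(rows) + 1]] <- rec(sprintf("PF%02d", g), "f.st",
                                    sprintf("f.s%d", g), ax, 4000 + g, 3,
                                    30, 5000 + g * 60, 0)
  for (g in 1:35)
    rows[[length(rows) + 1]] <- rec(sprintf("PG%02d", g), "g.st",
                                    sprintf("g.s%d", g), ax, 5000 + g, 3,
                                    50 + g, 3000, 0)
  records <- do.call(rbind, rows)
  # scanner diversity inside the retained subset: 12 of the fillers are 3 T,
  # 8 are from a different vendor
  fill_rows <- which(records$patient_id %in% sprintf("PE%02d", 1:25))
  records$field_strength[fill_rows[1:12]] <- 3.0
  records$manufacturer[fill_rows[13:20]] <- "OTHERVENDOR"
  list(records = records,
       expected = list(
         n_total = 200,          # 40 + 15 + 10 + 30 + 25 + 45 + 35
         n_after_te_tr = 120,    # 45 TR-excluded + 35 TE-excluded drop out
         n_after_scanner = 100,  # 12 at 3 T + 8 other-vendor drop out
         n_central14 = 14,       # slices 8..21 of the 30-slice series
         central_lo = 8, central_hi = 21,
         n_pairs = 30))          # 20 x 1 + 5 x 2
}

# finite-difference directional derivative helper
fd_dir <- function(f, x, i, eps = 1e-5) {
  xp <- x; xp[i] <- xp[i] + eps
  xm <- x; xm[i] <- xm[i] - eps
  (f(xp) - f(xm)) / (2 * eps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
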