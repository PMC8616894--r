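fx <- make_records_fixture()

test_that("TR/TE filters are inclusive at the bounds", {
  r <- fx$records
  kept <- filter_records(r, tr_max = 5000, te_max = 50)
  expect_false(any(kept$tr_ms > 5000))
  # a record at exactly TE 50 / TR 5000 is retained
  boundary <- data.frame(r[1, , drop = FALSE])
  boundary$te_ms <- 50; boundary$tr_ms <- 5000
  expect_equal(nrow(filter_records(boundary)), 1)
  over <- boundary; over$tr_ms <- 6000
  expect_equal(nrow(filter_records(over)), 0)
  # hand count on 5 toy TE values
  toy <- do.call(rbind, replicate(5, boundary, simplify = FALSE))
  toy$te_ms <- c(10, 30, 50, 55, 70)
  expect_equal(nrow(filter_records(toy, te_max = 50)), 3)
  # order preserved
  expect_equal(filter_records(toy, te_max = 50)$te_ms, c(10, 30, 50))
})

test_that("central-slice selection uses the centered window", {
  series <- fx$records[fx$records$series_uid == "d.s1", ]
  sel <- select_central_slices(series, 14)
  expect_equal(sort(sel$slice_index), fx$expected$central_lo:fx$expected$central_hi)
  # short series are returned whole
  short <- series[series$slice_index < 10, ]
  short$n_slices <- 10
  expect_equal(nrow(select_central_slices(short, 14)), 10)
  # exact-length series is the identity
  exact <- series[series$slice_index < 14, ]
  exact$n_slices <- 14
  expect_equal(select_central_slices(exact, 14)$slice_index, 0:13)
  mixed <- series
  mixed$series_uid[1] <- "other"
  expect_error(select_central_slices(mixed, 14), "series_uid")
})

test_that("five-attribute pairing emits ordered non-FS to target pairs", {
  r <- fx$records
  two <- r[r$patient_id == "PA01", ]
  p <- pair_images(two)
  expect_equal(nrow(p), 1)
  expect_equal(two$fs[p$source_row], 0)
  expect_equal(two$fs[p$target_row], 1)
  # slice locations 2 tolerances apart never pair
  apart <- two
  apart$slice_location <- c(10, 10 + 1.0)
  expect_equal(nrow(pair_images(apart, slice_location_tol = 0.5)), 0)
  # one source, two targets: two ordered pairs
  three <- r[r$patient_id == "PB01", ]
  expect_equal(nrow(pair_images(three)), 2)
})

test_that("filter-select-pair reproduces the fixture's frozen hand counts", {
  r <- fx$records
  expect_equal(nrow(r), fx$expected$n_total)
  kept <- filter_records(r, 5000, 50)
  expect_equal(nrow(kept), fx$expected$n_after_te_tr)
  kept2 <- filter_records(kept, 5000, 50, field_strength = 1.5,
                          manufacturer = "SIEMENS")
  expect_equal(nrow(kept2), fx$expected$n_after_scanner)
  sel <- select_central_slices(kept[kept$series_uid == "d.s1", ], 14)
  expect_equal(nrow(sel), fx$expected$n_central14)
  expect_equal(nrow(pair_images(kept)), fx$expected$n_pairs)
})

test_that("the final pair set is invariant under record permutation", {
  r <- filter_records(fx$records, 5000, 50)
  p1 <- pair_images(r)
  set.seed(1)
  perm <- sample(nrow(r))
  p2 <- pair_images(r[perm, ])
  key <- function(p, rr) sort(paste(rr$series_uid[p$source_row],
                                    rr$series_uid[p$target_row]))
  expect_equal(key(p1, r), key(p2, r[perm, ]))
})

test_that("pairing a fully paired synthetic manifest recovers the generator pairs", {
  ds <- tiny_dataset()
  rec <- dataset_records(ds)
  p <- pair_images(rec)
  got <- unique(t(apply(cbind(rec$sample_id[p$source_row],
                              rec$sample_id[p$target_row]), 1, sort)))
  m <- ds$meta
  want <- t(sapply(sort(unique(m$pair_id)), function(pid)
    sort(m$sample_id[which(m$pair_id == pid)])))
  expect_equal(got[order(got[, 1]), ], want[order(want[, 1]), ])
})

test_that("preprocess rescales to [-1,1], resizes bilinearly and is idempotent", {
  img <- matrix(runif(36, 0, 400), 6)
  out <- preprocess(img, 6)
  expect_equal(min(out), -1)
  expect_equal(max(out), 1)
  expect_true(all(preprocess(matrix(5, 4, 4), 4) == -1))
  # independent bilinear check (half-pixel convention, edge clamped)
  x <- matrix(c(0, 1, 1, 0), 2, 2)
  got <- matrix(mrcgan:::cpp_bilinear_resize(array(x, c(2, 2, 1, 1)), 4, 4), 4, 4)
  bil <- function(i, j) {
    si <- min(max((i + 0.5) / 2 - 0.5, 0), 1)
    sj <- min(max((j + 0.5) / 2 - 0.5, 0), 1)
    f0 <- x[1, 1] * (1 - sj) + x[1, 2] * sj
    f1 <- x[2, 1] * (1 - sj) + x[2, 2] * sj
    f0 * (1 - si) + f1 * si
  }
  want <- outer(0:3, 0:3, Vectorize(bil))
  expect_lt(max(abs(got - want)), 1e-12)
  # idempotence on an already scaled, already sized image
  once <- preprocess(img, 8)
  expect_lt(max(abs(preprocess(once, 8) - once)), 1e-6)
})

test_that("augmentation is deterministic, identity at zero settings, and shifts trace", {
  img <- matrix(runif(64^2, -1, 1), 64)
  expect_lt(max(abs(augment(img, 1, max_shift = 0, zoom_range = c(1, 1)) - img)),
            1e-12)
  expect_identical(augment(img, 5), augment(img, 5))
  expect_false(identical(augment(img, 5), augment(img, 6)))
  # a pure +2-column shift moves a bright pixel by two columns
  dot <- matrix(0, 16, 16)
  dot[8, 8] <- 1
  shifted <- matrix(mrcgan:::cpp_affine_sample(array(dot, c(16, 16, 1, 1)),
                                               0, 2, 1), 16, 16)
  expect_equal(shifted[8, 10], 1)
  expect_equal(sum(shifted), 1)
  expect_error(augment(img, 1, max_shift = 0.7), "max_shift")
  expect_error(augment(img, 1, zoom_range = c(0.2, 1)), "zoom_range")
})
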