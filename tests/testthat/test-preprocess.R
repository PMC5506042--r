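test_that("subarray partition follows the stepped edge-anchored layout", {
  w <- partition_subarrays(100, 100)
  expect_equal(nrow(w), 9)
  expect_equal(sort(unique(w$row_start)), c(0, 25, 50))

  # full-size grid: starts derived independently by stepping then anchoring
  w2 <- partition_subarrays(1002, 1002)
  starts <- seq(0, 1002 - 50, by = 25)
  if (max(starts) + 50 < 1002) starts <- c(starts, 1002 - 50)
  expect_equal(sort(unique(w2$row_start)), starts)
  expect_equal(nrow(w2), length(starts)^2)
  expect_equal(nrow(w2), 1600)

  w3 <- partition_subarrays(50, 50)
  expect_equal(nrow(w3), 1)

  expect_error(subsub_config(subarray_size = 50, overlap = 50), "overlap")
})

test_that("every probe is covered by 1-4 windows (more near anchored edges)", {
  for (len in c(100, 1002)) {
    w <- partition_subarrays(len, len)
    cnt <- matrix(0L, len, len)
    for (i in seq_len(nrow(w))) {
      ri <- w$row_start[i] + seq_len(w$size[i])
      ci <- w$col_start[i] + seq_len(w$size[i])
      cnt[ri, ci] <- cnt[ri, ci] + 1L
    }
    expect_gte(min(cnt), 1L)
    # the edge-anchored window adds a third layer per axis, so coverage is
    # at most 3 per axis: 9 in the far corner, 6 on an anchored edge
    expect_lte(max(cnt), 9L)
    interior <- cnt[100:(len - 100), 100:(len - 100), drop = FALSE]
    if (length(interior) > 0) expect_lte(max(interior), 4L)
  }
})

test_that("piecewise LTS recovers clean linear relationships exactly", {
  withr::with_seed(11, {
    x <- rnorm(200, 8, 1.5)
  })
  f <- fit_piecewise_lts(x, x)
  expect_equal(unname(f$coefficients[["b1"]]), 1, tolerance = 1e-10)
  expect_equal(unname(f$coefficients[["b0"]]), 0, tolerance = 1e-9)
  expect_lt(f$trimmed_rss, 1e-18)
  expect_equal(predict(f, x), x, tolerance = 1e-12)

  f3 <- fit_piecewise_lts(x, x + 3)
  expect_equal(f3$segments$slope, c(1, 1), tolerance = 1e-8)
  expect_equal(f3$segments$intercept, c(3, 3), tolerance = 1e-7)
})

test_that("piecewise LTS ignores gross outliers", {
  withr::with_seed(12, {
    x <- runif(20, 0, 10)
  })
  y <- 2 * x
  y[1:4] <- y[1:4] + 50
  f <- fit_piecewise_lts(x, y)
  expect_equal(f$segments$slope, c(2, 2), tolerance = 1e-6)
  expect_equal(f$segments$intercept, c(0, 0), tolerance = 1e-6)
  # matches the independent exhaustive-subset oracle on the same instance
  o <- oracle_piecewise_lts(x, y)
  expect_equal(f$trimmed_rss, o$obj, tolerance = 1e-9)
})

test_that("exact LTS equals the exhaustive oracle on small instances", {
  withr::with_seed(13, {
    for (i in 1:10) {
      n <- sample(8:12, 1)
      x <- runif(n, 0, 10)
      y <- 1.5 * x - 2 + rnorm(n, sd = 0.3)
      n_out <- sample(0:2, 1)
      if (n_out > 0) y[seq_len(n_out)] <- y[seq_len(n_out)] + 25
      f <- fit_piecewise_lts(x, y)
      o <- oracle_piecewise_lts(x, y)
      expect_equal(f$trimmed_rss, o$obj, tolerance = 1e-8)
    }
  })
})

test_that("constant target intensities fall back to a flagged flat fit", {
  f <- fit_piecewise_lts(rep(5, 30), rnorm(30))
  expect_true(f$degenerate)
  expect_equal(unname(f$coefficients[["b1"]]), 0)
})

test_that("self-normalization is the identity", {
  chip <- generate_probe_chip(side = 120, artifact = "blotch", noise_sd = 0.1,
                              seed = 21)$target
  out <- subsub_normalize(chip, chip)
  expect_equal(out$intensity, chip$intensity, tolerance = 1e-12)
  expect_lt(max(abs(out$intensity - chip$intensity)), 1e-10)
})

test_that("constant shifts are absorbed by the window intercepts", {
  withr::with_seed(22, {
    ref <- matrix(rnorm(100 * 100, 8, 1.5), 100, 100)
  })
  # global shift: every window sees a pure offset, recovery is exact
  tgt <- probe_chip(ref + 0.8)
  out <- subsub_normalize(tgt, probe_chip(ref))
  expect_equal(out$intensity, ref, tolerance = 1e-9)

  # regional shift: all cells further than one window from the boundary
  # belong only to single-regime windows and are recovered exactly
  tgt2 <- ref
  tgt2[, 1:50] <- tgt2[, 1:50] + 0.8
  out2 <- subsub_normalize(probe_chip(tgt2), probe_chip(ref))
  pure <- c(1:25, 76:100)
  expect_equal(out2$intensity[, pure], ref[, pure], tolerance = 1e-9)
  err_in <- mean(abs(tgt2 - ref))
  err_out <- mean(abs(out2$intensity - ref))
  expect_lt(err_out, err_in / 4)
})

test_that("gradient artifacts shrink in every subarray after normalization", {
  fx <- generate_probe_chip(side = 150, artifact = "gradient", noise_sd = 0.05,
                            magnitude = 1, seed = 23)
  out <- subsub_normalize(fx$target, fx$reference)
  w <- partition_subarrays(150, 150)
  for (i in seq_len(nrow(w))) {
    ri <- w$row_start[i] + seq_len(w$size[i])
    ci <- w$col_start[i] + seq_len(w$size[i])
    before <- mean(abs(fx$target$intensity[ri, ci] - fx$reference$intensity[ri, ci]))
    after <- mean(abs(out$intensity[ri, ci] - fx$reference$intensity[ri, ci]))
    expect_lt(after, before)
  }
  expect_error(subsub_normalize(fx$target, probe_chip(matrix(1, 3, 3))),
               "geometry")
})

test_that("probe-chip summarization recovers additive chip effects", {
  beta <- c(ref = 0, s1 = 1.2, s2 = -0.4, s3 = 0.7)
  chips <- additive_chips(beta)
  prof <- summarize_ptr(chips, references = "ref")
  expect_equal(colnames(prof$values), c("s1", "s2", "s3"))
  # chip-effect differences are recovered exactly
  got <- prof$values["S01", ] - prof$values["S01", "s1"]
  expect_equal(unname(got), unname(beta[2:4] - beta["s1"]), tolerance = 1e-10)
})

test_that("probe-level corruption is absorbed by the probe effect", {
  beta <- c(ref = 0, s1 = 1.2, s2 = -0.4, s3 = 0.7)
  chips <- additive_chips(beta)
  clean <- summarize_ptr(chips, references = "ref")

  # same probe shifted on every chip: expression unchanged
  shifted <- lapply(chips, function(ch) {
    ch$intensity[4, ] <- ch$intensity[4, ] + 5
    ch
  })
  prof_all <- summarize_ptr(shifted, references = "ref")
  expect_equal(prof_all$values, clean$values, tolerance = 1e-8)

  # one probe on one chip: deviation stays below the naive 5/11 mean shift
  one <- lapply(chips, function(ch) ch)
  one$s2$intensity[4, 2] <- one$s2$intensity[4, 2] + 5
  prof_one <- summarize_ptr(one, references = "ref")
  dev <- abs(prof_one$values["S02", "s2"] - clean$values["S02", "s2"])
  expect_lt(dev, 5 / 11)
})

test_that("probesets with fewer than two probes fall back and are flagged", {
  map <- matrix(c("A", "A", "A", "B"), 2, 2)
  chips <- list(
    ref = probe_chip(matrix(c(5, 6, 7, 3), 2, 2), map),
    s1 = probe_chip(matrix(c(6, 7, 8, 4), 2, 2), map)
  )
  prof <- summarize_ptr(chips, references = "ref")
  expect_equal(attr(prof, "flagged_probesets"), "B")
  expect_equal(unname(prof$values["B", "s1"]), 4)
})

test_that("chip TSVs round-trip through the raw-intensity representation", {
  fx <- generate_probe_chip(side = 20, artifact = "blotch", seed = 30)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_chip_tsv(fx$target, path)
  back <- read_chip_tsv(path)
  expect_equal(back$intensity, fx$target$intensity, tolerance = 1e-9)
  expect_identical(back$probeset, fx$target$probeset)
})
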