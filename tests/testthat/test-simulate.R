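test_that("noise-free generation has exactly the planted rank", {
  E1 <- generate_profile(simulation_spec(
    n_genes = 300, noise_sd = 0, exo_strength = 0, seed = 1
  ))$profile$values
  expect_equal(sum(svd(E1)$d > 1e-8), 1)

  E2 <- generate_profile(simulation_spec(n_genes = 300, noise_sd = 0, seed = 1))
  sv <- svd(E2$profile$values)
  expect_equal(sum(sv$d > 1e-8), 2)
  # exact recovery of planted singular values and gene eigenvectors
  expect_equal(sv$d[1:2], c(E2$truth$endo_rho, E2$truth$exo_rho), tolerance = 1e-12)
  expect_equal(abs(sum(sv$u[, 1] * E2$truth$endo_u)), 1, tolerance = 1e-10)
  expect_equal(abs(sum(sv$u[, 2] * E2$truth$exo_u)), 1, tolerance = 1e-10)
})

test_that("planted loadings are orthogonal, week-monotone and control-free", {
  for (seed in 1:5) {
    sim <- generate_profile(simulation_spec(n_genes = 100, seed = seed))
    tr <- sim$truth
    att <- sim$profile$samples
    expect_lt(abs(sum(tr$endo_v * tr$exo_v)), 1e-12)
    expect_equal(sqrt(sum(tr$endo_v^2)), 1, tolerance = 1e-12)
    expect_equal(sqrt(sum(tr$exo_v^2)), 1, tolerance = 1e-12)
    expect_lt(abs(sum(tr$endo_u * tr$exo_u)), 1e-12)
    # endogenous loading increases with age in every sample
    expect_true(all(diff(tr$endo_v[order(att$week)]) >= -1e-12))
    # exogenous loading is exactly zero on control samples
    expect_lt(max(abs(tr$exo_v[att$diet == "RC"])), 1e-12)
  }
})

test_that("leading gene eigenvectors are recovered at the default noise level", {
  cosines <- vapply(1:10, function(seed) {
    sim <- generate_profile(simulation_spec(seed = seed))
    sv <- svd(sim$profile$values)
    c(abs(sum(sv$u[, 1] * sim$truth$endo_u)),
      abs(sum(sv$u[, 2] * sim$truth$exo_u)))
  }, numeric(2))
  expect_true(all(cosines >= 0.95))
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- generate_profile(simulation_spec(n_genes = 60, seed = 5))
  b <- generate_profile(simulation_spec(n_genes = 60, seed = 5))
  d <- generate_profile(simulation_spec(n_genes = 60, seed = 6))
  expect_identical(a$profile$values, b$profile$values)
  expect_identical(a$truth$endo_u, b$truth$endo_u)
  expect_false(identical(a$profile$values, d$profile$values))
})

test_that("degenerate sample layouts are refused", {
  expect_error(
    generate_profile(simulation_spec(n_genes = 20, weeks = 9,
                                     planted_set_size = 5)),
    "degenerate"
  )
})

test_that("probe chip generator honors artifact contracts", {
  clean <- generate_probe_chip(side = 100, artifact = "none", noise_sd = 0, seed = 2)
  expect_identical(clean$target$intensity, clean$reference$intensity)

  grad <- generate_probe_chip(side = 100, artifact = "gradient", noise_sd = 0.02,
                              magnitude = 1, seed = 3)
  w <- partition_subarrays(100, 100)
  shift <- vapply(seq_len(nrow(w)), function(i) {
    ri <- w$row_start[i] + seq_len(w$size[i])
    ci <- w$col_start[i] + seq_len(w$size[i])
    mean(grad$target$intensity[ri, ci] - grad$reference$intensity[ri, ci])
  }, numeric(1))
  by_row <- tapply(shift, w$row_start, mean)
  expect_true(all(diff(by_row[order(as.numeric(names(by_row)))]) > 0))

  again <- generate_probe_chip(side = 100, artifact = "gradient", noise_sd = 0.02,
                               magnitude = 1, seed = 3)
  expect_identical(grad$target$intensity, again$target$intensity)
})

test_that("gene set generator plants at the requested extreme", {
  sim <- generate_profile(simulation_spec(n_genes = 300, seed = 4))
  gs <- generate_genesets(sim$truth, n_null_sets = 20, set_size = 25, seed = 1)
  planted <- attr(gs, "planted")
  u <- sim$truth$exo_u
  r <- rank(u)
  expect_gt(mean(r[planted$members]), length(u) / 2)
  expect_true(all(planted$members %in% gs$universe))
  expect_length(gs, 21)
  expect_error(generate_genesets(sim$truth, set_size = 0), "set_size")

  # null sets score uniformly against the planted eigenvector
  p <- vapply(setdiff(names(gs$sets), planted$name), function(nm) {
    wilcoxon_score(u, gs$sets[[nm]], end = "high")$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("promoter generator plants consensus occurrences by rank", {
  sim <- generate_profile(simulation_spec(n_genes = 200, seed = 8))
  m <- pwm_from_consensus("AGGTCA", id = "halfsite")

  # rate 1 for the top 50: all carry an exact consensus occurrence
  pr <- generate_promoters(sim$truth, m, promoter_length = 120,
                           planting_rate_by_rank = rep(1, 50),
                           background_rate = 0, seed = 1)
  top50 <- names(sort(sim$truth$exo_u, decreasing = TRUE))[1:50]
  expect_true(all(grepl("AGGTCA", pr[top50], fixed = TRUE)))

  # rate 0 everywhere: consensus occurrences match the background expectation
  pr0 <- generate_promoters(sim$truth, m, promoter_length = 120,
                            planting_rate_by_rank = rep(0, 50),
                            background_rate = 0, seed = 2)
  rc <- "TGACCT"
  hits <- grepl("AGGTCA", pr0, fixed = TRUE) | grepl(rc, pr0, fixed = TRUE)
  p_gene <- 1 - (1 - 0.25^6)^(2 * (120 - 6 + 1))
  expected <- length(pr0) * p_gene
  expect_lt(abs(sum(hits) - expected), 4 * sqrt(expected) + 3)

  expect_identical(
    generate_promoters(sim$truth, m, promoter_length = 80, seed = 3),
    generate_promoters(sim$truth, m, promoter_length = 80, seed = 3)
  )
  expect_error(generate_promoters(sim$truth, m, promoter_length = 4), "longer")
})
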