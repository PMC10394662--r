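test_that("noiseless generation is a passthrough of the forward model", {
  design <- experiment_design()
  ds_none <- generate_dataset(design, noise_spec("none"))
  ds_zero <- generate_dataset(design, noise_spec(sigma = 0), seed = 7)
  sim <- simulate_profile(k = design$k_true, times = design$times)
  expect_equal(profile_matrix(ds_none), profile_matrix(sim))
  expect_equal(profile_matrix(ds_zero), profile_matrix(sim))
})

test_that("generation is deterministic in the seed and records provenance", {
  design <- experiment_design()
  a <- generate_dataset(design, noise_spec(sigma = 0.02), seed = 11)
  b <- generate_dataset(design, noise_spec(sigma = 0.02), seed = 11)
  c <- generate_dataset(design, noise_spec(sigma = 0.02), seed = 12)
  expect_identical(profile_matrix(a), profile_matrix(b))
  expect_false(identical(profile_matrix(a), profile_matrix(c)))
  meta <- profile_meta(a)
  expect_equal(meta$seed, 11)
  expect_equal(meta$noise$sigma, 0.02)
  expect_equal(meta$k_true, rate_constants(design$k_true))
  expect_error(generate_dataset(design, noise_spec(sigma = 0.02)), "seed")
})

test_that("multiplicative noise has the requested relative spread", {
  # frozen system (all k = 0, all concentrations 1) -> 10^4 replicate cells
  design <- experiment_design(times = seq_len(1112), c0 = rep(1, 9),
                              k_true = rep(0, 12))
  ds <- generate_dataset(design, noise_spec(sigma = 0.02), seed = 3)
  cells <- as.numeric(profile_matrix(ds))
  expect_gte(length(cells), 1e4)
  expect_equal(stats::sd(cells), 0.02, tolerance = 0.05)
  expect_equal(mean(cells), 1, tolerance = 0.005)
})

test_that("negative noisy concentrations are clipped to zero", {
  design <- experiment_design(times = c(0, 10, 20), c0 = c(1e-4, rep(0, 8)),
                              k_true = rep(0, 12))
  ds <- generate_dataset(design, noise_spec("additive_gaussian", sigma = 0.1),
                         seed = 5)
  expect_true(all(profile_matrix(ds) >= 0))
  raw <- generate_dataset(design,
                          noise_spec("additive_gaussian", sigma = 0.1,
                                     clip_negative = FALSE), seed = 5)
  expect_true(any(profile_matrix(raw) < 0))
})

test_that("CSV round trip is exact and schema violations are caught", {
  ds <- generate_dataset(experiment_design(), noise_spec(sigma = 0.02),
                         seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(ds, path)
  back <- read_profile_csv(path)
  expect_identical(profile_matrix(back), profile_matrix(ds))
  expect_identical(back$time_min, ds$time_min)

  # missing species column
  df <- utils::read.csv(path)
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[, setdiff(names(df), "H")], p2, row.names = FALSE)
  expect_error(read_profile_csv(p2), "H")

  # shuffled rows break monotone time
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[c(2, 1, 3:10), ], p3, row.names = FALSE)
  expect_error(read_profile_csv(p3), "increasing")

  # negative time
  df$time_min[1] <- -5
  p4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, p4, row.names = FALSE)
  expect_error(read_profile_csv(p4), "negative time")

  expect_error(read_profile_csv("does-not-exist.csv"), "not found")
})

test_that("noisy replicate fits are centred on the generating constant", {
  k_true <- ref_k()
  design <- experiment_design()
  est2 <- vapply(1:200, function(s) {
    ds <- generate_dataset(design, noise_spec(sigma = 0.02), seed = 300 + s)
    fit_kinetics(ds, c0 = pure_A())$estimates[["k2"]]
  }, numeric(1))
  bias <- (mean(est2) - k_true[["k2"]]) / k_true[["k2"]]
  expect_lt(abs(bias), 0.02)
})

test_that("the generator-fitter loop recovers the generating constants", {
  ds <- generate_dataset(experiment_design(), noise_spec("none"))
  fit <- fit_kinetics(ds)
  k_true <- profile_meta(ds)$k_true
  free <- k_true > 0
  expect_lt(max(abs(fit$estimates[free] - k_true[free]) / k_true[free]),
            1e-3)
  expect_true(all(fit$at_bound[!free]))
})
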