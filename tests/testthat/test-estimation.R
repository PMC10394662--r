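test_that("sum of squared residuals behaves like a pooled L2 objective", {
  net <- default_network()
  k <- ref_k()
  ds <- generate_dataset(experiment_design(), noise_spec("none"))
  expect_lt(sum_squared_residuals(ds, net, k, c0 = pure_A()), 1e-18)

  # a single perturbed cell contributes exactly its squared offset
  delta <- 3e-3
  bumped <- ds
  bumped$E[4] <- bumped$E[4] + delta
  expect_equal(sum_squared_residuals(bumped, net, k, c0 = pure_A()),
               delta^2, tolerance = 1e-8)
})

test_that("ssr per cell converges to the noise variance", {
  sigma <- 5e-3
  design <- experiment_design(times = seq_len(1112), c0 = rep(1, 9),
                              k_true = rep(0, 12))
  ds <- generate_dataset(design,
                         noise_spec("additive_gaussian", sigma = sigma,
                                    clip_negative = FALSE), seed = 9)
  ssr <- sum_squared_residuals(ds, default_network(), rep(0, 12),
                               c0 = rep(1, 9))
  n <- nrow(ds) * 9
  expect_equal(ssr / n, sigma^2, tolerance = 0.05)
})

test_that("noiseless fits recover random generating constants exactly", {
  net <- default_network()
  for (seed in 1:5) {
    k_true <- random_k(seed)
    ds <- generate_dataset(experiment_design(k_true = k_true),
                           noise_spec("none"))
    fit <- fit_kinetics(ds, net)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$estimates - k_true) / k_true), 1e-3)
  }
})

test_that("constants generated at zero land on the bound and carry no interval", {
  k_true <- ref_k() # k8 = k9 = 0
  ds <- generate_dataset(experiment_design(k_true = k_true),
                         noise_spec("none"))
  fit <- fit_kinetics(ds)
  expect_true(all(fit$at_bound[c(8, 9)]))
  expect_false(any(fit$at_bound[-c(8, 9)]))
  expect_true(all(is.na(fit$hpd95[c(8, 9)])))
  expect_true(all(is.na(correlation_matrix(fit)[8, -8])))
})

test_that("degenerate datasets are rejected up front", {
  ds <- generate_dataset(experiment_design(), noise_spec("none"))
  expect_error(fit_kinetics(ds[, c("time_min", "B")]), "under-determined")
  expect_error(fit_kinetics(ds[1, ]), "at least 2 time points")
})

test_that("estimates are invariant to a rescaling of all concentrations", {
  ds <- generate_dataset(experiment_design(), noise_spec(sigma = 0.02),
                         seed = 21)
  scaled <- ds
  alpha <- 7.3
  scaled[LETTERS[1:9]] <- scaled[LETTERS[1:9]] * alpha
  f1 <- fit_kinetics(ds, c0 = pure_A())
  f2 <- fit_kinetics(scaled, c0 = alpha * pure_A())
  # the optimum is exactly scale-equivariant; termination points differ
  # by ~1e-4 relative on the weakly identified constants
  expect_equal(f2$estimates, f1$estimates, tolerance = 1e-3)
  expect_equal(f2$ssr, alpha^2 * f1$ssr, tolerance = 1e-4)
})

test_that("correlation matrix is a proper correlation over free parameters", {
  ds <- generate_dataset(experiment_design(), noise_spec(sigma = 0.02),
                         seed = 31)
  fit <- fit_kinetics(ds, c0 = pure_A())
  m <- correlation_matrix(fit)
  free <- which(!fit$at_bound)
  expect_equal(unname(diag(m)[free]), rep(1, length(free)))
  expect_equal(m[free, free], t(m)[free, free], tolerance = 1e-12)
  expect_true(all(abs(m[free, free]) <= 1 + 1e-12))
})

test_that("denser sampling never loses information (Laplace widths shrink)", {
  net <- default_network()
  k <- ref_k()
  widths <- function(times) {
    ds <- generate_dataset(experiment_design(times = times),
                           noise_spec("none"))
    resid_fn <- function(kk) {
      K <- build_rate_matrix(net, pmax(kk, 0))
      as.numeric(as.matrix(ds[, LETTERS[1:9]]) -
                   ppdkinetics:::predict_conc(K, as.data.frame(ds),
                                              pure_A()))
    }
    unc <- ppdkinetics:::laplace_uncertainty(
      k, at_bound = k == 0, resid_fn = resid_fn, sigma2 = 1, scale = 0.01
    )
    unc$hpd95[k > 0]
  }
  w10 <- widths(seq(0, 360, length.out = 10))
  w20 <- widths(seq(0, 360, length.out = 20))
  expect_true(all(w20 <= w10 * (1 + 1e-10)))
})

test_that("HPD of Gaussian samples reproduces the normal quantile", {
  withr::local_seed(42)
  x <- stats::rnorm(20000)
  ci <- hpd_interval(x, level = 0.95)
  expect_equal((ci[2] - ci[1]) / 2, stats::qnorm(0.975), tolerance = 0.03)
  expect_error(hpd_interval(x, level = 0), "strictly between")
  expect_error(hpd_interval(x, level = 1), "strictly between")
  expect_error(hpd_interval(stats::rnorm(50)), "at least 100")
})

test_that("MCMC and Laplace uncertainties agree on a well-identified constant", {
  ds <- generate_dataset(experiment_design(), noise_spec(sigma = 0.02),
                         seed = 51)
  cfg_l <- fit_config(uncertainty = "laplace")
  cfg_m <- fit_config(uncertainty = "mcmc", mcmc_draws = 1500,
                      mcmc_burnin = 500, mcmc_seed = 4)
  f_l <- fit_kinetics(ds, config = cfg_l, c0 = pure_A())
  f_m <- fit_kinetics(ds, config = cfg_m, c0 = pure_A())
  expect_equal(f_m$estimates, f_l$estimates, tolerance = 1e-8)
  expect_false(is.null(f_m$samples))
  ratio <- f_m$hpd95[["k2"]] / f_l$hpd95[["k2"]]
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})
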