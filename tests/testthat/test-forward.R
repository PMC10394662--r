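test_that("frozen and trivial propagation cases hold", {
  net <- default_network()
  prof0 <- simulate_profile(net, rep(0, 12), times = c(0, 100, 360))
  for (i in 1:3) {
    expect_equal(as.numeric(prof0[i, LETTERS[1:9]]), c(1, rep(0, 8)))
  }
  prof <- simulate_profile(net, ref_k(), times = c(0, 360))
  expect_equal(as.numeric(prof[1, LETTERS[1:9]]), c(1, rep(0, 8)))
})

test_that("reactant decay follows the closed-form exponential", {
  prof <- simulate_profile(k = ref_k(), times = default_times())
  ktot <- sum(ref_k()[1:4])
  expect_equal(prof$A, exp(-ktot * default_times()), tolerance = 1e-12)
  expect_equal(prof$A[10], exp(-7.969e-3 * 360), tolerance = 1e-12)
})

test_that("matrix-exponential propagation matches the adaptive ODE oracle", {
  net <- default_network()
  draws <- c(list(ref_k()), lapply(1:20, random_k_with_zeros))
  for (k in draws) {
    a <- profile_matrix(simulate_profile(net, k, times = default_times()))
    b <- profile_matrix(ode_oracle(net, k, times = default_times()))
    expect_lt(max(abs(a - b)), 1e-8)
  }
})

test_that("mass is conserved and monotonicity holds along every profile", {
  net <- default_network()
  for (seed in 1:10) {
    k <- random_k_with_zeros(seed)
    prof <- simulate_profile(net, k, times = default_times())
    m <- profile_matrix(prof)
    expect_lt(max(abs(rowSums(m) - 1)), 1e-10)
    if (sum(k[1:4]) > 0) expect_true(all(diff(prof$A) < 0))
    for (d in c("F", "G", "H", "I")) {
      expect_true(all(diff(prof[[d]]) >= -1e-14))
    }
  }
})

test_that("propagation is linear in the initial state and a semigroup in time", {
  net <- default_network()
  k <- ref_k()
  c0 <- c(1, rep(0, 8))
  p1 <- profile_matrix(simulate_profile(net, k, c0, times = c(0, 90, 250)))
  p3 <- profile_matrix(simulate_profile(net, k, 3 * c0, times = c(0, 90, 250)))
  expect_equal(p3, 3 * p1, tolerance = 1e-12)

  # propagate to 250 directly vs via the state at 90
  mid <- as.numeric(p1[2, ])
  p_via <- profile_matrix(simulate_profile(net, k, mid, times = c(160)))
  expect_lt(max(abs(p_via - p1[3, , drop = FALSE])), 1e-12)
})

test_that("Bateman closed forms reproduce the matrix solution", {
  net <- default_network()
  k <- ref_k()
  ktot <- sum(k[1:4])
  grid <- seq(0, 360, length.out = 10)
  prof <- simulate_profile(net, k, times = grid)
  k_in <- c(B = k[["k2"]], C = k[["k4"]], D = k[["k3"]], E = k[["k1"]])
  k_out <- c(B = k[["k5"]] + k[["k6"]], C = k[["k7"]] + k[["k9"]],
             D = k[["k11"]] + k[["k12"]], E = k[["k8"]] + k[["k10"]])
  for (sp in names(k_in)) {
    cf <- bateman_intermediate(grid, k_in[[sp]], k_out[[sp]], ktot)
    expect_lt(max(abs(cf - prof[[sp]])), 1e-10)
  }
  expect_equal(bateman_intermediate(0, 1e-3, 2e-3, 5e-3), 0)
})

test_that("the equal-rate Bateman limit is continuous", {
  t <- seq(0, 500, by = 25)
  kp <- 2e-3
  exact_limit <- bateman_intermediate(t, 1e-3, kp, kp)
  expect_equal(exact_limit, 1e-3 * t * exp(-kp * t))
  nearby <- bateman_intermediate(t, 1e-3, kp, kp * (1 + 1e-9))
  expect_lt(max(abs(nearby - exact_limit)), 1e-9)
})

test_that("peak times match a fine grid search of the simulated profile", {
  expect_equal(time_of_maximum(0.01, 0.01), 100)
  expect_true(is.na(time_of_maximum(0, 5e-3)))
  expect_true(is.na(time_of_maximum(5e-3, 0)))

  k <- ref_k()
  tmax <- time_of_maximum(k_out = k[["k5"]] + k[["k6"]],
                          k_parent_total = sum(k[1:4]))
  # independent oracle: grid search of the simulated B-component
  grid <- seq(200, 260, by = 0.01)
  prof <- simulate_profile(k = k, times = grid)
  expect_equal(tmax, grid[which.max(prof$B)], tolerance = 1e-4)
  expect_equal(tmax, 232.7, tolerance = 1e-3)
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(simulate_profile(k = ref_k(), times = c(10, 5)),
               "strictly increasing")
  expect_error(simulate_profile(k = ref_k(), times = c(-1, 5)),
               "nonnegative")
  expect_error(simulate_profile(k = ref_k(), c0 = rep(-1, 9)),
               "nonnegative")
  expect_error(bateman_intermediate(1, -1e-3, 1e-3, 1e-3), "nonnegative")
  expect_error(time_of_maximum(-1e-3, 1e-3), "nonnegative")
})
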