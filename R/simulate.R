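default_c0 <- function() {
  stats::setNames(c(1, rep(0, 8)), LETTERS[1:9])
}

check_c0 <- function(c0) {
  if (is.null(c0)) return(default_c0())
  if (!is.numeric(c0) || length(c0) != 9) {
    stop("`c0` must be a numeric vector of 9 concentrations (A..I)",
         call. = FALSE)
  }
  if (anyNA(c0) || any(c0 < 0)) {
    stop("`c0` entries must be nonnegative and non-missing", call. = FALSE)
  }
  if (sum(c0) <= 0) stop("`c0` must have at least one positive entry",
                         call. = FALSE)
  stats::setNames(as.numeric(c0), LETTERS[1:9])
}

check_times <- function(times) {
  if (!is.numeric(times) || length(times) < 1 || anyNA(times)) {
    stop("`times` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(times < 0)) stop("`times` must be nonnegative", call. = FALSE)
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  as.numeric(times)
}

new_kin_profile <- function(df, meta = list()) {
  tibble::new_tibble(df, meta = meta, class = "kin_profile")
}

#' Metadata of a concentration profile
#'
#' @param profile A `kin_profile` tibble.
#' @return The provenance list stored on the profile (source, seed, noise,
#'   generating rate constants where applicable).
#' @export
profile_meta <- function(profile) attr(profile, "meta") %||% list()

#' Simulate concentration-time profiles
#'
#' Solves the linear system `dc/dt = K c` exactly by matrix-exponential
#' propagation, `c(t) = expm(K t) c0`, at each requested time. The
#' exponential uses scaling-and-squaring (via \pkg{Matrix}), which is robust
#' to repeated or near-equal rates.
#'
#' @param network A `kin_network`; defaults to [default_network()].
#' @param k Rate constants (min^-1), see [rate_constants()].
#' @param c0 Initial concentrations for species A..I (arbitrary units);
#'   default pure reactant, `A = 1`.
#' @param times Strictly increasing sampling times in minutes, all `>= 0`.
#' @return A `kin_profile` tibble with columns `time_min`, `A`..`I`.
#' @examples
#' prof <- simulate_profile(k = reference_rate_constants()$estimate,
#'                          times = seq(0, 360, by = 40))
#' prof
#' @export
simulate_profile <- function(network = default_network(), k, c0 = NULL,
                             times = seq(0, 360, by = 40)) {
  k <- rate_constants(k)
  c0 <- check_c0(c0)
  times <- check_times(times)
  K <- build_rate_matrix(network, k)
  conc <- propagate(K, c0, times)
  df <- tibble::as_tibble(cbind(data.frame(time_min = times),
                                as.data.frame(conc)))
  new_kin_profile(df, meta = list(source = "simulated", k = k, c0 = c0))
}

propagate <- function(K, c0, times) {
  conc <- matrix(0, length(times), 9, dimnames = list(NULL, colnames(K)))
  for (i in seq_along(times)) {
    if (times[i] == 0) {
      conc[i, ] <- c0
    } else {
      E <- as.matrix(Matrix::expm(Matrix::Matrix(K * times[i])))
      conc[i, ] <- as.numeric(E %*% c0)
    }
  }
  conc
}

#' Brute-force ODE integration oracle
#'
#' Integrates `dc/dt = K c` with an adaptive solver (\pkg{deSolve}, `lsoda`,
#' rtol = atol = 1e-12). Exists as an independent cross-check of
#' [simulate_profile()]; the matrix-exponential path is the one used
#' throughout the package.
#'
#' @inheritParams simulate_profile
#' @return A `kin_profile` tibble, as [simulate_profile()].
#' @export
ode_oracle <- function(network = default_network(), k, c0 = NULL,
                       times = seq(0, 360, by = 40)) {
  if (!requireNamespace("deSolve", quietly = TRUE)) {
    stop("ode_oracle() requires the deSolve package", call. = FALSE)
  }
  k <- rate_constants(k)
  c0 <- check_c0(c0)
  times <- check_times(times)
  K <- build_rate_matrix(network, k)
  t_solve <- if (times[1] == 0) times else c(0, times)
  sol <- deSolve::ode(
    y = c0, times = t_solve,
    func = function(t, y, parms) list(as.numeric(K %*% y)),
    parms = NULL, method = "lsoda", rtol = 1e-12, atol = 1e-12
  )
  conc <- sol[match(times, sol[, "time"]), LETTERS[1:9], drop = FALSE]
  df <- tibble::as_tibble(cbind(data.frame(time_min = times),
                                as.data.frame(conc)))
  new_kin_profile(df, meta = list(source = "ode_oracle", k = k, c0 = c0))
}

#' Closed-form concentration of a first-order intermediate
#'
#' The Bateman solution for an intermediate `X` in the chain
#' `A -> X -> products`: formed from `A` at rate `k_in`, consumed at total
#' rate `k_out`, while `A` itself decays at total rate `k_parent_total`
#' (the sum over all routes leaving `A`). Per unit initial `A`,
#' `x(t) = k_in (exp(-k_out t) - exp(-k_parent_total t)) /
#' (k_parent_total - k_out)`. The difference of exponentials is evaluated
#' through `expm1`, which removes the catastrophic cancellation near the
#' equal-rate degeneracy and passes continuously through the removable
#' singularity, where the value is the limit `k_in t exp(-k_out t)`.
#'
#' @param t Time(s) in minutes.
#' @param k_in Formation rate constant from the parent (min^-1).
#' @param k_out Total consumption rate constant of the intermediate (min^-1).
#' @param k_parent_total Total decay rate constant of the parent (min^-1).
#' @param c0 Initial parent concentration (default 1).
#' @return Intermediate concentration(s), same length as `t`.
#' @export
bateman_intermediate <- function(t, k_in, k_out, k_parent_total, c0 = 1) {
  if (any(c(k_in, k_out, k_parent_total) < 0)) {
    stop("rate constants must be nonnegative", call. = FALSE)
  }
  dk <- k_parent_total - k_out
  # (exp(-a t) - exp(-b t)) / (b - a) = t exp(-a t) * (-expm1(-dk t))/(dk t)
  x <- dk * t
  phi <- ifelse(abs(x) < 1e-12, 1, -expm1(-x) / x)
  c0 * k_in * t * exp(-k_out * t) * phi
}

#' Time at which an intermediate peaks
#'
#' For a first-order intermediate with formation driven by a parent decaying
#' at total rate `k_parent_total` and consumption at total rate `k_out`, the
#' interior maximum sits at `ln(k_parent_total / k_out) /
#' (k_parent_total - k_out)` (equal rates: `1 / k_parent_total`). The peak
#' time does not depend on the formation rate constant, which only scales
#' the amplitude. A terminal species (`k_out = 0`) accumulates
#' monotonically and has no interior maximum; nothing forms when
#' `k_parent_total = 0`. Both cases return `NA`.
#'
#' @inheritParams bateman_intermediate
#' @return Peak time in minutes, or `NA_real_` when no interior maximum
#'   exists.
#' @export
time_of_maximum <- function(k_out, k_parent_total) {
  if (any(c(k_out, k_parent_total) < 0)) {
    stop("rate constants must be nonnegative", call. = FALSE)
  }
  if (k_parent_total == 0 || k_out == 0) return(NA_real_)
  if (abs(k_parent_total - k_out) < 1e-12 * max(k_parent_total, k_out)) {
    return(1 / k_parent_total)
  }
  log(k_parent_total / k_out) / (k_parent_total - k_out)
}

profile_matrix <- function(profile) {
  as.matrix(profile[, LETTERS[1:9]])
}

#' Plot a concentration profile
#'
#' Draws the nine concentration-time curves, faceted by species role
#' (reactant / hydroxyketones / diols) as the profiles are usually shown.
#'
#' @param object A `kin_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kin_profile
#' @export
autoplot.kin_profile <- function(object, ...) {
  role_of <- stats::setNames(species_table()$role, species_table()$code)
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time_min",
                              names_to = "species", values_to = "conc")
  long$role <- factor(role_of[long$species],
                      levels = c("reactant", "hydroxyketone", "diol"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$conc,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$role), scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "concentration (a.u.)",
                  colour = "species")
}
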