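#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a kinetic fit
#'
#' One row per rate constant: the estimate, the 95% marginal HPD
#' half-width and bounds, and whether the constant sits at the lower bound
#' (at-bound constants carry no interval).
#'
#' @param x A `kin_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `hpd95`, `conf.low`,
#'   `conf.high`, `one_sided`, `at_bound`.
#' @method tidy kin_fit
#' @export
tidy.kin_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    hpd95 = unname(x$hpd95),
    conf.low = unname(x$conf.low),
    conf.high = unname(x$conf.high),
    one_sided = unname(x$one_sided),
    at_bound = unname(x$at_bound)
  )
}

#' One-row fit summary
#'
#' @param x A `kin_fit`.
#' @param ... Unused.
#' @return A tibble with `ssr`, `sigma`, `n_obs`, `n_free`, `converged`,
#'   `degenerate` and the uncertainty method used.
#' @method glance kin_fit
#' @export
glance.kin_fit <- function(x, ...) {
  tibble::tibble(
    ssr = x$ssr, sigma = x$sigma, n_obs = x$n_obs, n_free = x$n_free,
    converged = x$converged, degenerate = x$degenerate,
    uncertainty = x$config$uncertainty
  )
}

#' Plot observed data against the fitted model
#'
#' @param object A `kin_fit`.
#' @param ... Unused.
#' @return A ggplot object: observed points and fitted curves per species,
#'   faceted by species role.
#' @method autoplot kin_fit
#' @export
autoplot.kin_fit <- function(object, ...) {
  role_of <- stats::setNames(species_table()$role, species_table()$code)
  shape_long <- function(df, what) {
    out <- tidyr::pivot_longer(tibble::as_tibble(df), -"time_min",
                               names_to = "species", values_to = "conc")
    out$what <- what
    out
  }
  obs <- shape_long(object$data, "observed")
  fitted_dense <- simulate_profile(
    object$network, object$estimates,
    c0 = if (is.null(object$c0)) as.numeric(object$data[1, LETTERS[1:9]])
         else object$c0,
    times = seq(min(object$data$time_min), max(object$data$time_min),
                length.out = 73)
  )
  fit_l <- shape_long(fitted_dense, "fitted")
  obs$role <- factor(role_of[obs$species],
                     levels = c("reactant", "hydroxyketone", "diol"))
  fit_l$role <- factor(role_of[fit_l$species],
                       levels = c("reactant", "hydroxyketone", "diol"))
  ggplot2::ggplot(mapping = ggplot2::aes(.data$time_min, .data$conc,
                                         colour = .data$species)) +
    ggplot2::geom_line(data = fit_l) +
    ggplot2::geom_point(data = obs, size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$role), scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "concentration (a.u.)",
                  colour = "species")
}
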