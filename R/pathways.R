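#' Classify reaction pathways
#'
#' Partitions the eight two-step routes `A - X - Y` (reactant ->
#' hydroxyketone -> diol) into negligible, preferential and intermediate
#' classes, as a pure function of the rate constants and thresholds:
#' \itemize{
#'   \item an edge is \emph{negligible} when its rate constant is at or
#'     below `negligible_tol` (default 0, i.e. exactly at the lower bound);
#'     a route containing a negligible edge is negligible;
#'   \item among the remaining routes, a route `A - X - Y` is
#'     \emph{preferential} when its first leg is strictly the largest of
#'     the first legs feeding the same diol `Y` and its second leg is
#'     strictly the largest of the edges leaving the same hydroxyketone
#'     `X` (ties are reported, not broken);
#'   \item everything else is \emph{intermediate}.
#' }
#'
#' @param k Rate constants (min^-1).
#' @param network A `kin_network`.
#' @param negligible_tol Rate threshold (min^-1) below which an edge counts
#'   as negligible; default 0.
#' @return A `pathway_classification` list: `negligible_edges` (tibble of
#'   edges at or below the threshold), `routes` (tibble with `route`,
#'   `diol`, `k_first`, `k_second`, `class`, `tie`), and the threshold
#'   used.
#' @examples
#' classify_pathways(reference_rate_constants()$estimate)
#' @export
classify_pathways <- function(k, network = default_network(),
                              negligible_tol = 0) {
  if (negligible_tol < 0) stop("`negligible_tol` must be >= 0", call. = FALSE)
  k <- rate_constants(k)
  rx <- network$reactions
  rx$k <- unname(k[rx$index])

  first_leg <- rx[rx$source == "A", ]
  second_leg <- rx[rx$source != "A", ]
  routes <- dplyr::inner_join(
    first_leg, second_leg,
    by = dplyr::join_by("target" == "source"),
    suffix = c("_first", "_second")
  )
  routes <- tibble::tibble(
    route = paste("A", routes$target, routes$target_second, sep = "-"),
    via = routes$target, diol = routes$target_second,
    index_first = routes$index_first, index_second = routes$index_second,
    k_first = routes$k_first, k_second = routes$k_second
  )
  routes$negligible <- routes$k_first <= negligible_tol |
    routes$k_second <= negligible_tol

  routes$class <- ifelse(routes$negligible, "negligible", "intermediate")
  routes$tie <- FALSE
  for (i in which(!routes$negligible)) {
    same_diol <- routes$k_first[routes$diol == routes$diol[i]]
    same_branch <- routes$k_second[routes$via == routes$via[i]]
    first_max <- routes$k_first[i] == max(same_diol)
    second_max <- routes$k_second[i] == max(same_branch)
    first_tied <- first_max && sum(same_diol == max(same_diol)) > 1
    second_tied <- second_max && sum(same_branch == max(same_branch)) > 1
    if (first_max && second_max) {
      if (first_tied || second_tied) {
        routes$tie[i] <- TRUE
      } else {
        routes$class[i] <- "preferential"
      }
    }
  }

  neg_edges <- rx[rx$k <= negligible_tol,
                  c("index", "source", "target", "k")]
  structure(list(
    negligible_edges = tibble::as_tibble(neg_edges),
    routes = routes[order(routes$route),
                    c("route", "via", "diol", "k_first", "k_second",
                      "class", "tie")],
    negligible_tol = negligible_tol
  ), class = "pathway_classification")
}

#' @export
print.pathway_classification <- function(x, ...) {
  cat("<pathway_classification> threshold", x$negligible_tol, "min^-1\n")
  for (cl in c("preferential", "intermediate", "negligible")) {
    r <- x$routes$route[x$routes$class == cl]
    cat(sprintf("  %-12s %s\n", cl,
                if (length(r)) paste(r, collapse = ", ") else "(none)"))
  }
  if (any(x$routes$tie)) {
    cat("  ties:", paste(x$routes$route[x$routes$tie], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Regio- and enantioselectivity along a profile
#'
#' Derived selectivity metrics at each time point:
#' regioselectivity `(B + C) / (B + C + D + E)` — the fraction of first
#' hydrogenations occurring at the carbonyl next to the phenyl ring — and
#' enantiomeric excesses `ee(B vs C) = (B - C)/(B + C)` and
#' `ee(D vs E) = (D - E)/(D + E)`. Metrics with a zero denominator (e.g.
#' at `t = 0`, before any intermediate has formed) are reported as `NA`.
#'
#' @param profile A concentration profile (`kin_profile` or data frame
#'   with columns `time_min`, `A`..`I`).
#' @return A tibble with columns `time_min`, `regioselectivity`, `ee_BC`,
#'   `ee_DE`.
#' @export
selectivity_metrics <- function(profile) {
  df <- check_dataset(profile)
  safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tibble::tibble(
    time_min = df$time_min,
    regioselectivity = safe_ratio(df$B + df$C, df$B + df$C + df$D + df$E),
    ee_BC = safe_ratio(df$B - df$C, df$B + df$C),
    ee_DE = safe_ratio(df$D - df$E, df$D + df$E)
  )
}
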