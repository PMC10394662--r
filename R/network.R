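#' Species table for the hydrogenation network
#'
#' The nine species tracked by the model: the dione reactant `A`, the four
#' half-hydrogenated hydroxyketones `B`--`E` (one carbonyl reduced) and the
#' four fully hydrogenated diols `F`--`I`. Hydrogen, solvent, catalyst and
#' the cinchonidine modifier are not state variables; their effects are
#' lumped into the apparent first-order rate constants.
#'
#' @return A tibble with columns `code` and `role`
#'   (`reactant` / `hydroxyketone` / `diol`), in the fixed ordering
#'   `A, B, ..., I` used by every matrix and file in the package.
#' @export
species_table <- function() {
  tibble::tibble(
    code = LETTERS[1:9],
    role = c("reactant", rep("hydroxyketone", 4), rep("diol", 4))
  )
}

#' Default twelve-reaction hydrogenation network
#'
#' Builds the irreversible two-level reaction network for the hydrogenation
#' of 1-phenyl-1,2-propanedione: four parallel first hydrogenations of the
#' reactant `A` to the hydroxyketones `B`--`E`, followed by eight second
#' hydrogenations of the hydroxyketones to the diols `F`--`I`. Each reaction
#' carries a unique index `1..12` matching the rate-constant labels
#' `k1..k12`.
#'
#' The default index-to-edge assignment is
#' `k1: A->E`, `k2: A->B`, `k3: A->D`, `k4: A->C`, `k5: B->I`, `k6: B->F`,
#' `k7: C->H`, `k8: E->I`, `k9: C->G`, `k10: E->H`, `k11: D->F`,
#' `k12: D->G`. The assignment between `k5` and `k12` within
#' `{B->I, D->G}` is a package convention; supply a network YAML file (see
#' [read_network_yaml()]) to swap it without code changes.
#'
#' @return A `kin_network` object: a list with tibbles `species`
#'   (see [species_table()]) and `reactions` (`index`, `source`, `target`).
#' @examples
#' net <- default_network()
#' net$reactions
#' @export
default_network <- function() {
  reactions <- tibble::tibble(
    index  = 1:12,
    source = c("A", "A", "A", "A", "B", "B", "C", "E", "C", "E", "D", "D"),
    target = c("E", "B", "D", "C", "I", "F", "H", "I", "G", "H", "F", "G")
  )
  new_kin_network(species_table(), reactions)
}

new_kin_network <- function(species, reactions) {
  structure(list(species = species, reactions = reactions),
            class = "kin_network")
}

#' Build a network from a plain list
#'
#' Accepts the structure produced by reading a network YAML/JSON file:
#' a `species` character vector (or list of `{code, role}`) and a
#' `reactions` list of `{index, source, target}` entries.
#'
#' @param x A list with elements `species` and `reactions`.
#' @return A `kin_network` object (validated; see [validate_network()]).
#' @export
network_from_list <- function(x) {
  if (!is.list(x) || is.null(x$reactions)) {
    stop("network definition must be a list with a `reactions` element",
         call. = FALSE)
  }
  reactions <- purrr::map_dfr(x$reactions, function(r) {
    tibble::tibble(index = as.integer(r$index),
                   source = as.character(r$source),
                   target = as.character(r$target))
  })
  reactions <- dplyr::arrange(reactions, .data$index)
  net <- new_kin_network(species_table(), reactions)
  problems <- validate_network(net)
  if (length(problems) > 0) {
    stop("invalid network definition:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  net
}

#' Read a network definition from a YAML file
#'
#' @param path Path to a YAML file with `species:` and `reactions:` keys.
#'   The file shipped at
#'   `system.file("extdata", "network.yaml", package = "ppdkinetics")`
#'   reproduces [default_network()].
#' @return A validated `kin_network` object.
#' @export
read_network_yaml <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path, call. = FALSE)
  network_from_list(yaml::read_yaml(path))
}

#' Validate a reaction network
#'
#' Checks the structural invariants of the two-level hydrogenation network:
#' twelve uniquely indexed reactions; sources and targets drawn from the
#' nine species; the reactant has exactly four outgoing edges (one per
#' hydroxyketone); each hydroxyketone has exactly two outgoing edges to
#' diols; each diol has exactly two incoming edges and none outgoing.
#'
#' @param network A `kin_network` object.
#' @return A character vector of human-readable violations; empty when the
#'   network is valid. Violations are returned, never raised.
#' @export
validate_network <- function(network) {
  problems <- character()
  sp <- network$species
  rx <- network$reactions
  if (nrow(sp) != 9 || !identical(sp$code, LETTERS[1:9])) {
    problems <- c(problems, "expected species A..I in order")
  }
  if (nrow(rx) != 12) {
    problems <- c(problems,
                  sprintf("expected 12 reactions, found %d", nrow(rx)))
  }
  if (!setequal(rx$index, seq_len(nrow(rx))) || anyDuplicated(rx$index) > 0) {
    problems <- c(problems, "reaction indices must cover 1..n exactly once")
  }
  bad_code <- setdiff(c(rx$source, rx$target), sp$code)
  if (length(bad_code) > 0) {
    problems <- c(problems,
                  paste0("unknown species code(s): ",
                         paste(bad_code, collapse = ", ")))
  }
  role_of <- stats::setNames(sp$role, sp$code)
  for (i in seq_len(nrow(rx))) {
    src <- rx$source[i]; tgt <- rx$target[i]
    if (!src %in% sp$code || !tgt %in% sp$code) next
    ok <- (role_of[src] == "reactant" && role_of[tgt] == "hydroxyketone") ||
      (role_of[src] == "hydroxyketone" && role_of[tgt] == "diol")
    if (!ok) {
      problems <- c(problems,
                    sprintf("edge k%d: %s->%s does not follow the hydrogenation order (reactant->hydroxyketone or hydroxyketone->diol)",
                            rx$index[i], src, tgt))
    }
  }
  deg_out <- table(factor(rx$source, levels = sp$code))
  deg_in  <- table(factor(rx$target, levels = sp$code))
  if (deg_out[["A"]] != 4) {
    problems <- c(problems,
                  sprintf("reactant A must have 4 outgoing edges, found %d",
                          deg_out[["A"]]))
  }
  for (s in sp$code[sp$role == "hydroxyketone"]) {
    if (deg_out[[s]] != 2) {
      problems <- c(problems,
                    sprintf("hydroxyketone %s must have 2 outgoing edges, found %d",
                            s, deg_out[[s]]))
    }
  }
  for (s in sp$code[sp$role == "diol"]) {
    if (deg_in[[s]] != 2 || deg_out[[s]] != 0) {
      problems <- c(problems,
                    sprintf("diol %s must have 2 incoming and 0 outgoing edges, found %d in / %d out",
                            s, deg_in[[s]], deg_out[[s]]))
    }
  }
  problems
}

#' Validate and normalise a rate-constant vector
#'
#' @param k Numeric vector of 12 apparent first-order rate constants
#'   (min^-1), optionally named `k1..k12`; names are checked when present.
#' @return A named numeric vector `k1..k12`.
#' @export
rate_constants <- function(k) {
  if (!is.numeric(k) || length(k) != 12) {
    stop("`k` must be a numeric vector of length 12 (k1..k12), got length ",
         length(k), call. = FALSE)
  }
  if (!is.null(names(k)) && !identical(names(k), paste0("k", 1:12))) {
    stop("`k` names must be k1..k12 in order", call. = FALSE)
  }
  if (anyNA(k)) stop("`k` must not contain NA", call. = FALSE)
  neg <- which(k < 0)
  if (length(neg) > 0) {
    stop("rate constants must be nonnegative; offending index: k",
         paste(neg, collapse = ", k"), call. = FALSE)
  }
  stats::setNames(as.numeric(k), paste0("k", 1:12))
}

#' Published rate constants for the Ir/TiO2 / cinchonidine system
#'
#' The fitted apparent rate constants reported for the cinchonidine-modified
#' Ir/TiO2-catalysed hydrogenation of 1-phenyl-1,2-propanedione at room
#' temperature and 40 bar, with their 95% marginal HPD half-widths. `k8`
#' and `k9` sit at the imposed zero lower bound and carry no interval
#' (the corresponding routes `E->I` and `C->G` are negligible).
#'
#' @return A tibble with columns `term` (`k1..k12`), `estimate` (min^-1),
#'   `hpd95` (half-width, min^-1; `NA` for at-bound constants) and
#'   `at_bound`.
#' @examples
#' k <- reference_rate_constants()$estimate
#' sum(k[1:4]) # total consumption rate of the reactant
#' @export
reference_rate_constants <- function() {
  tibble::tibble(
    term = paste0("k", 1:12),
    estimate = c(0.821, 3.175, 1.472, 2.501, 0.199, 1.776, 2.285,
                 0, 0, 0.241, 0.359, 0.617) * 1e-3,
    hpd95 = c(0.099, 0.248, 0.124, 0.221, 0.019, 0.325, 0.484,
              NA, NA, 0.780, 0.516, 0.084) * 1e-3,
    at_bound = c(rep(FALSE, 7), TRUE, TRUE, rep(FALSE, 3))
  )
}

#' Build the rate matrix of the linear ODE system
#'
#' Assembles the 9x9 first-order generator `K` of `dc/dt = K c`:
#' `K[target, source] = k(edge)` for every reaction and each diagonal entry
#' is minus the total consumption rate of its species, so every column sums
#' to zero (closed mass balance, 1:1 stoichiometry).
#'
#' @param network A `kin_network` object.
#' @param k Rate constants, as accepted by [rate_constants()].
#' @return A 9x9 numeric matrix (min^-1) with species codes as dimnames.
#' @examples
#' K <- build_rate_matrix(default_network(), reference_rate_constants()$estimate)
#' colSums(K) # all zero
#' @export
build_rate_matrix <- function(network, k) {
  stopifnot(inherits(network, "kin_network"))
  k <- rate_constants(k)
  codes <- network$species$code
  K <- matrix(0, 9, 9, dimnames = list(codes, codes))
  rx <- network$reactions
  for (i in seq_len(nrow(rx))) {
    rate <- k[[rx$index[i]]]
    K[rx$target[i], rx$source[i]] <- K[rx$target[i], rx$source[i]] + rate
    K[rx$source[i], rx$source[i]] <- K[rx$source[i], rx$source[i]] - rate
  }
  K
}

#' @export
print.kin_network <- function(x, ...) {
  cat("<kin_network> 9 species, ", nrow(x$reactions), " reactions\n", sep = "")
  rx <- x$reactions
  cat(paste0("  k", rx$index, ": ", rx$source, " -> ", rx$target,
             collapse = "\n"), "\n")
  invisible(x)
}
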