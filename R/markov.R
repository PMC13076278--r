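#' Estimate a one-step Markov transition matrix from state sequences
#'
#' Counts transitions between consecutive years within each region and
#' row-normalizes to maximum-likelihood transition probabilities. Gaps in a
#' region's year sequence break the chain (no bridging); rows with zero
#' observed origins are flagged undefined, never imputed.
#'
#' @param states a state panel from [classify_states()] (columns
#'   `region_id`, `year`, `state`).
#' @param regions optional region-id subset.
#' @param years optional year range (numeric vector; its min/max bound the
#'   window; transitions are counted between consecutive years inside it).
#' @param n_states number of states K; defaults to the panel's
#'   `threshold_spec` or the maximum observed state.
#' @return Object of class `"transition_estimate"`: list with `counts`
#'   (K x K integer), `probabilities` (row-stochastic; `NA` rows where
#'   undefined), `n_transitions`, `undefined_rows`, `n_states`.
#' @examples
#' s <- data.frame(region_id = "A", year = 1:5, state = c(1, 2, 1, 2, 2))
#' estimate_transitions(s, n_states = 3)$counts
#' @export
estimate_transitions <- function(states, regions = NULL, years = NULL,
                                 n_states = NULL) {
  req <- c("region_id", "year", "state")
  miss <- setdiff(req, names(states))
  if (length(miss)) stop("states lacks columns: ", paste(miss, collapse = ", "))
  spec <- attr(states, "threshold_spec")
  if (is.null(n_states)) {
    n_states <- if (!is.null(spec)) spec$n_states else max(states$state)
  }
  if (!is.null(regions)) states <- states[states$region_id %in% regions, ]
  if (!is.null(years)) {
    states <- states[states$year >= min(years) & states$year <= max(years), ]
  }
  if (!nrow(states)) stop("empty subset: no state observations selected")
  if (any(states$state < 1 | states$state > n_states)) {
    stop("states outside 1..", n_states)
  }

  pairs <- transition_pairs(states)
  K <- n_states
  counts <- matrix(0L, K, K)
  if (nrow(pairs)) {
    tab <- table(factor(pairs$state, levels = 1:K),
                 factor(pairs$state_next, levels = 1:K))
    counts <- matrix(as.integer(tab), K, K)
  }
  row_tot <- rowSums(counts)
  probs <- counts / ifelse(row_tot > 0, row_tot, NA_real_)
  undefined <- which(row_tot == 0)
  structure(list(counts = counts, probabilities = probs,
                 n_transitions = sum(counts), undefined_rows = undefined,
                 n_states = K, threshold_spec = spec),
            class = "transition_estimate")
}

# consecutive-year (state_t, state_{t+1}) pairs per region; gaps break chains
transition_pairs <- function(states) {
  ord <- order(states$region_id, states$year)
  s <- states[ord, ]
  same_region <- s$region_id[-nrow(s)] == s$region_id[-1]
  consecutive <- diff(s$year) == 1
  idx <- which(same_region & consecutive)
  data.frame(region_id = s$region_id[idx], year = s$year[idx],
             state = s$state[idx], state_next = s$state[idx + 1L])
}

#' @export
print.transition_estimate <- function(x, digits = 4, ...) {
  cat("One-step transition estimate (K = ", x$n_states, ", ",
      x$n_transitions, " transitions)\n", sep = "")
  print(round(x$probabilities, digits))
  if (length(x$undefined_rows)) {
    cat("undefined rows (no origins):",
        paste(x$undefined_rows, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Stationary distribution of a transition matrix
#'
#' Solves `pi P = pi` with `sum(pi) = 1` by a direct linear solve on
#' `t(P) - I` augmented with the normalization row. Irreducibility is checked
#' first via strong connectivity of the positive-entry digraph; for a
#' reducible chain no unique stationary vector exists and an
#' absorbing-structure report (the recurrent classes) is returned instead.
#'
#' @param x a `"transition_estimate"` (all rows must be defined) or a
#'   row-stochastic K x K matrix.
#' @return Object of class `"stationary_distribution"`: list with `pi`
#'   (or `NULL` if reducible), `irreducible`, `aperiodic` (`TRUE` when some
#'   diagonal entry is positive — sufficient condition — else `NA`), and
#'   `recurrent_classes` (state index sets of closed communicating classes,
#'   only for reducible chains).
#' @examples
#' stationary_distribution(reference_transition_matrix())$pi
#' @export
stationary_distribution <- function(x) {
  if (inherits(x, "transition_estimate")) {
    if (length(x$undefined_rows)) {
      stop("transition matrix has undefined rows (",
           paste(x$undefined_rows, collapse = ", "),
           "); stationary distribution is not computed for such subsets")
    }
    P <- x$probabilities
  } else {
    P <- as.matrix(x)
  }
  K <- nrow(P)
  if (ncol(P) != K) stop("P must be square")
  if (any(P < -1e-12) || any(abs(rowSums(P) - 1) > 1e-6)) {
    stop("P must be row-stochastic")
  }

  g <- igraph::graph_from_adjacency_matrix(P > 1e-15, mode = "directed")
  irr <- igraph::is_connected(g, mode = "strong")
  if (!irr) {
    comp <- igraph::components(g, mode = "strong")$membership
    closed <- vapply(seq_len(max(comp)), function(cc) {
      inside <- comp == cc
      sum(P[inside, !inside, drop = FALSE]) < 1e-15
    }, logical(1))
    rec <- lapply(which(closed), function(cc) which(comp == cc))
    return(structure(list(pi = NULL, irreducible = FALSE, aperiodic = NA,
                          recurrent_classes = rec, P = P),
                     class = "stationary_distribution"))
  }

  A <- rbind(t(P) - diag(K), rep(1, K))
  pi_hat <- unname(qr.solve(A, c(rep(0, K), 1)))
  pi_hat[pi_hat < 0 & pi_hat > -1e-12] <- 0
  if (any(pi_hat < 0) || abs(sum(pi_hat) - 1) > 1e-10 ||
      max(abs(drop(pi_hat %*% P) - pi_hat)) > 1e-10) {
    stop("stationary solve failed its own residual checks")
  }
  structure(list(pi = pi_hat, irreducible = TRUE,
                 aperiodic = if (any(diag(P) > 0)) TRUE else NA,
                 recurrent_classes = NULL, P = P),
            class = "stationary_distribution")
}

#' @export
print.stationary_distribution <- function(x, digits = 4, ...) {
  if (x$irreducible) {
    cat("Stationary distribution:", round(x$pi, digits), "\n")
  } else {
    cat("Chain is reducible; recurrent classes:\n")
    for (rc in x$recurrent_classes) cat(" {", paste(rc, collapse = ","), "}\n")
  }
  invisible(x)
}

#' Persistence and mobility summary of a transition estimate
#'
#' Reports the diagonal self-retention probabilities, per-row off-diagonal
#' mass, the mobility index `1 - trace(P)/K` (0 for a frozen chain,
#' `(K-1)/K` for uniform rows), and flags "no cross-tier leap" cells:
#' non-adjacent transitions with zero estimated probability.
#'
#' @param estimate a `"transition_estimate"`.
#' @param stationary optional `"stationary_distribution"` to include.
#' @return List with `diagonal`, `off_diagonal_mass`, `mobility_index`,
#'   `zero_leap_cells` (matrix of i,j indices), and `stationary_pi`.
#' @export
persistence_report <- function(estimate, stationary = NULL) {
  P <- estimate$probabilities
  K <- estimate$n_states
  defined <- setdiff(seq_len(K), estimate$undefined_rows)
  dg <- diag(P)
  leap <- which(abs(row(P) - col(P)) > 1 & P == 0, arr.ind = TRUE)
  list(
    diagonal = dg,
    off_diagonal_mass = rowSums(P) - dg,
    mobility_index = if (length(defined) == K) 1 - sum(dg) / K else NA_real_,
    zero_leap_cells = leap,
    undefined_rows = estimate$undefined_rows,
    stationary_pi = if (!is.null(stationary)) stationary$pi else NULL
  )
}
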