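#' Configuration for the synthetic efficiency panel generator
#'
#' Bundles and validates every knob of the synthetic data-generating process.
#' Defaults emulate the study conditions of the provincial healthcare panel:
#' 31 regions observed for 20 years, three inputs (physicians, nurses, beds)
#' and two outputs (outpatient visits, inpatient admissions), a latent
#' 3-state inefficiency process following the published transition matrix
#' ([reference_transition_matrix()]), and state inefficiency levels
#' (0.78, 0.90, 1.00) placing the pooled mean pure technical efficiency near
#' the published 0.884. The top state sits on the frontier (level 1), so DEA
#' has a well-defined frontier.
#'
#' @param n_regions,n_years panel dimensions (positive integers).
#' @param n_inputs,n_outputs numbers of input and output quantities.
#' @param true_transition K x K row-stochastic latent transition matrix.
#' @param state_inefficiency_levels per-state mean radial efficiency factors
#'   in (0, 1]; the level of the highest state must be exactly 1.
#' @param noise_sd standard deviation of log-scale idiosyncratic input noise
#'   (>= 0); 0 places every unit exactly at its efficiency-scaled frontier
#'   requirement.
#' @param spatial_coupling probability in `[0, 1]` that a region copies a
#'   uniformly chosen neighbour's latent state each step instead of drawing
#'   from its own kernel row.
#' @param adjacency_scheme `"grid_lattice"` (rook adjacency on the nearest
#'   rectangle, unused cells dropped) or `"supplied_edge_list"` (a
#'   [spatial_weights()] object must be passed to [generate_panel()]).
#' @param covariate_effects list with numeric named vectors `upward` and
#'   `downward`: signed effects of (demeaned) covariates on the upward /
#'   downward transition propensity of the latent process. Empty = no
#'   tilting.
#' @param seed integer RNG seed; identical configs give byte-identical
#'   panels.
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_regions = 31, n_years = 20,
                         n_inputs = 3, n_outputs = 2,
                         true_transition = reference_transition_matrix(),
                         state_inefficiency_levels = c(0.78, 0.90, 1.00),
                         noise_sd = 0.02, spatial_coupling = 0,
                         adjacency_scheme = c("grid_lattice",
                                              "supplied_edge_list"),
                         covariate_effects = list(upward = NULL,
                                                  downward = NULL),
                         seed = 1L) {
  adjacency_scheme <- match.arg(adjacency_scheme)
  stopifnot(n_regions >= 1, n_years >= 1, n_inputs >= 1, n_outputs >= 1,
            noise_sd >= 0, spatial_coupling >= 0, spatial_coupling <= 1)
  P <- unname(as.matrix(true_transition))
  K <- nrow(P)
  if (ncol(P) != K) stop("true_transition must be square")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12)) {
    stop("true_transition rows must be nonnegative and sum to 1 (within 1e-12)")
  }
  lev <- as.numeric(state_inefficiency_levels)
  if (length(lev) != K) stop("state_inefficiency_levels must have length K")
  if (any(lev <= 0 | lev > 1)) stop("inefficiency levels must be in (0, 1]")
  if (lev[K] != 1) stop("the highest state's level must be exactly 1 ",
                        "(frontier units must exist)")
  eff <- covariate_effects
  if (!is.list(eff)) stop("covariate_effects must be a list")
  eff$upward <- eff$upward %||% numeric(0)
  eff$downward <- eff$downward %||% numeric(0)
  structure(list(n_regions = as.integer(n_regions),
                 n_years = as.integer(n_years),
                 n_inputs = as.integer(n_inputs),
                 n_outputs = as.integer(n_outputs),
                 true_transition = P, n_states = K,
                 state_inefficiency_levels = lev,
                 noise_sd = noise_sd, spatial_coupling = spatial_coupling,
                 adjacency_scheme = adjacency_scheme,
                 covariate_effects = eff, seed = as.integer(seed)),
            class = "synth_config")
}

#' Rook-adjacency weights for the synthetic regions
#'
#' Lays `n_regions` out row-major on an `r x c` lattice (default
#' `r = floor(sqrt(n))`, `c = ceiling(n/r)`; trailing unused cells dropped)
#' and connects horizontally / vertically adjacent cells.
#'
#' @param config a `"synth_config"`, or a plain region count.
#' @param dims optional explicit `c(rows, cols)` lattice dimensions with
#'   `rows * cols >= n_regions`.
#' @return A [spatial_weights()] object over regions `R01..Rnn`.
#' @export
generate_adjacency <- function(config, dims = NULL) {
  n <- if (inherits(config, "synth_config")) config$n_regions else
    as.integer(config)
  ids <- region_ids(n)
  if (n == 1) return(spatial_weights(edges = NULL, regions = ids))
  if (is.null(dims)) {
    r <- max(1L, floor(sqrt(n)))
    dims <- c(r, ceiling(n / r))
  }
  if (prod(dims) < n) stop("lattice dims too small for n_regions")
  cell <- seq_len(n) - 1L
  row_i <- cell %/% dims[2]
  col_i <- cell %% dims[2]
  from <- to <- integer(0)
  right <- which(col_i < dims[2] - 1 & cell + 1 < n)
  down <- which(cell + dims[2] < n)
  from <- c(cell[right] + 1L, cell[down] + 1L)
  to <- c(cell[right] + 2L, cell[down] + dims[2] + 1L)
  spatial_weights(edges = data.frame(from = ids[from], to = ids[to]),
                  regions = ids)
}

region_ids <- function(n) sprintf("R%02d", seq_len(n))

# exogenous covariate draws: region random intercepts + mild trends + noise
synth_covariate_table <- function(config) {
  n <- config$n_regions; T_ <- config$n_years
  yrs <- 2000L + seq_len(T_)
  ids <- region_ids(n)
  base <- list(doctor_nurse_ratio = c(mu = 0.96, re = 0.15, tr = 0.000, e = 0.08),
               staff_per_10k     = c(mu = 60,   re = 12,   tr = 0.80,  e = 3),
               beds_per_staff    = c(mu = 0.63, re = 0.06, tr = 0.003, e = 0.04),
               ln_gdp_pc         = c(mu = 10.0, re = 0.40, tr = 0.050, e = 0.08))
  out <- data.frame(region_id = rep(ids, each = T_), year = rep(yrs, n))
  tc <- seq_len(T_) - (T_ + 1) / 2   # centred trend
  for (nm in names(base)) {
    p <- base[[nm]]
    re <- rnorm(n, 0, p["re"])
    out[[nm]] <- rep(re, each = T_) + p["mu"] + rep(tc, n) * p["tr"] +
      rnorm(n * T_, 0, p["e"])
  }
  out
}

# tilt one kernel row by upward shift u and downward shift d (mass moved
# between the diagonal and the adjacent cells, clipped to keep a valid row)
tilt_row <- function(p, i, K, u, d) {
  if (i < K && u != 0) {
    delta <- min(max(u, -p[i + 1]), p[i])
    p[i + 1] <- p[i + 1] + delta
    p[i] <- p[i] - delta
  }
  if (i > 1 && d != 0) {
    delta <- min(max(d, -p[i - 1]), p[i])
    p[i - 1] <- p[i - 1] + delta
    p[i] <- p[i] - delta
  }
  p
}

#' Generate a synthetic production panel with known ground truth
#'
#' Simulates the full data-generating process: (1) a latent per-region
#' K-state Markov chain for radial inefficiency, started from the stationary
#' distribution of `true_transition`, optionally spatially coupled (a region
#' copies a random neighbour's previous state with probability
#' `spatial_coupling`) and optionally tilted by covariates; (2) region-scaled
#' log-normal outputs; (3) inputs built as the deterministic frontier input
#' requirement for the drawn outputs, divided by the unit's true efficiency,
#' times multiplicative log-normal noise. The frontier input requirement is
#' `x_k(y) = a_k + sum_r b_kr * (y_r / base_r)^gamma` with `gamma = 1.2`
#' (convex and increasing in outputs, so the implied technology set is convex
#' and noise-free frontier units score exactly 1 under BCC DEA).
#'
#' @param config a `"synth_config"`.
#' @param weights optional [spatial_weights()]; required when
#'   `adjacency_scheme = "supplied_edge_list"`, generated on the fly for
#'   `"grid_lattice"` when `spatial_coupling > 0`.
#' @return List with `panel` (data frame `region_id`, `year`, input and
#'   output columns, with `input_cols` / `output_cols` attributes) and
#'   `truth` (list: `latent_states`, `true_efficiency`, `frontier_spec`,
#'   `covariates` — non-`NULL` only when covariate effects are configured).
#' @export
generate_panel <- function(config, weights = NULL) {
  if (!inherits(config, "synth_config")) stop("config must be a synth_config")
  n <- config$n_regions; T_ <- config$n_years; K <- config$n_states
  P <- config$true_transition
  ids <- region_ids(n)
  yrs <- 2000L + seq_len(T_)

  if (config$spatial_coupling > 0) {
    if (is.null(weights)) {
      if (config$adjacency_scheme == "supplied_edge_list") {
        stop("supplied_edge_list scheme needs a spatial_weights object")
      }
      weights <- generate_adjacency(config)
    }
    nbrs <- neighbour_list(weights)[ids]
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  tilting <- length(config$covariate_effects$upward) > 0 ||
    length(config$covariate_effects$downward) > 0
  covs <- if (tilting) synth_covariate_table(config) else NULL
  shift_up <- shift_down <- matrix(0, n, T_)
  if (tilting) {
    for (side in c("upward", "downward")) {
      b <- config$covariate_effects[[side]]
      if (!length(b)) next
      bad <- setdiff(names(b), names(covs))
      if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
      sh <- matrix(0, n, T_)
      for (nm in names(b)) {
        x <- matrix(covs[[nm]], nrow = T_)  # year x region
        sh <- sh + t(x - mean(x)) * b[[nm]]
      }
      if (side == "upward") shift_up <- sh else shift_down <- sh
    }
  }

  # latent chain
  S <- matrix(NA_integer_, n, T_)
  sd0 <- stationary_distribution(P)
  p0 <- if (sd0$irreducible) sd0$pi else rep(1 / K, K)
  S[, 1] <- sample.int(K, n, replace = TRUE, prob = p0)
  if (T_ > 1) for (t in 2:T_) {
    for (r in seq_len(n)) {
      if (config$spatial_coupling > 0 && length(nbrs[[r]]) &&
          runif(1) < config$spatial_coupling) {
        pick <- nbrs[[r]][sample.int(length(nbrs[[r]]), 1)]
        S[r, t] <- S[match(pick, ids), t - 1L]
      } else {
        row <- tilt_row(P[S[r, t - 1L], ], S[r, t - 1L], K,
                        shift_up[r, t - 1L], shift_down[r, t - 1L])
        S[r, t] <- sample.int(K, 1, prob = row)
      }
    }
  }

  # outputs: region scale heterogeneity x log-normal idiosyncratic variation
  out_base <- c(70, 3.7, rep(1, max(0, config$n_outputs - 2)))[
    seq_len(config$n_outputs)]
  region_scale <- rlnorm(n, 0, 0.35)
  Y <- array(NA_real_, c(n, T_, config$n_outputs))
  for (k in seq_len(config$n_outputs)) {
    Y[, , k] <- region_scale * out_base[k] *
      matrix(rlnorm(n * T_, 0, 0.10), n, T_)
  }

  # frontier input requirement, convex & increasing in outputs
  gamma <- 1.2
  in_base <- c(7, 8.2, 20, rep(5, max(0, config$n_inputs - 3)))[
    seq_len(config$n_inputs)]
  a <- 0.3 * in_base
  b <- matrix(rep(0.35 * in_base, config$n_outputs),
              config$n_inputs, config$n_outputs)
  frontier_input <- function(y) {  # y: vector of outputs
    a + drop(b %*% (y / out_base)^gamma)
  }

  eff <- matrix(config$state_inefficiency_levels[S], n, T_)
  X <- array(NA_real_, c(n, T_, config$n_inputs))
  for (r in seq_len(n)) for (t in seq_len(T_)) {
    noise <- if (config$noise_sd > 0) {
      exp(rnorm(config$n_inputs, 0, config$noise_sd))
    } else rep(1, config$n_inputs)
    X[r, t, ] <- frontier_input(Y[r, t, ]) / eff[r, t] * noise
  }

  input_cols <- c("physicians", "nurses", "beds",
                  paste0("input_", seq_len(max(0, config$n_inputs - 3)) + 3))[
                    seq_len(config$n_inputs)]
  output_cols <- c("outpatient", "inpatient",
                   paste0("output_", seq_len(max(0, config$n_outputs - 2)) + 2))[
                     seq_len(config$n_outputs)]
  panel <- data.frame(region_id = rep(ids, each = T_), year = rep(yrs, n))
  for (k in seq_along(input_cols)) {
    panel[[input_cols[k]]] <- as.vector(t(X[, , k]))
  }
  for (k in seq_along(output_cols)) {
    panel[[output_cols[k]]] <- as.vector(t(Y[, , k]))
  }
  attr(panel, "input_cols") <- input_cols
  attr(panel, "output_cols") <- output_cols

  truth <- list(
    latent_states = data.frame(region_id = rep(ids, each = T_),
                               year = rep(yrs, n),
                               state = as.vector(t(S))),
    true_efficiency = data.frame(region_id = rep(ids, each = T_),
                                 year = rep(yrs, n),
                                 efficiency = as.vector(t(eff))),
    frontier_spec = list(gamma = gamma, intercept = a, coef = b,
                         output_base = out_base),
    covariates = covs
  )
  list(panel = panel, truth = truth)
}

#' Covariate table for the transition equations
#'
#' Returns per region-year values of the four resource-structure covariates
#' used by the transition equations: doctor-nurse ratio, health staff per
#' 10k population, beds per staff, and log GDP per capita. When the config
#' specifies covariate effects, the covariates were already drawn inside
#' [generate_panel()] (they tilt the latent process there) and the stashed
#' table is returned; otherwise fresh exogenous covariates, independent of
#' the transitions, are drawn under the config seed.
#'
#' @param config the `"synth_config"` used to generate the panel.
#' @param truth the `truth` element returned by [generate_panel()].
#' @return Data frame `region_id`, `year`, `doctor_nurse_ratio`,
#'   `staff_per_10k`, `beds_per_staff`, `ln_gdp_pc`.
#' @export
generate_covariates <- function(config, truth) {
  if (!is.null(truth$covariates)) return(truth$covariates)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed + 1000003L)
  synth_covariate_table(config)
}
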