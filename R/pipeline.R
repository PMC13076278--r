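#' Run the full efficiency-dynamics analysis from one configuration
#'
#' Orchestrates the stages in dependency order — synthetic data (or supplied
#' files), DEA scoring, state classification, Markov transition /
#' stationary analysis, spatial Markov conditioning, and the transition
#' equations — writing every stage's tables as tab-delimited text plus a
#' machine-readable JSON manifest (stage, parameters, output files, md5
#' hashes). Identical config and seed give identical manifest hashes.
#'
#' @param config list with elements:
#'   * `synth`: a [synth_config()] (exactly one data source: either this or
#'     `files`);
#'   * `files`: list with paths `panel` (+ optional `adjacency`,
#'     `covariates`) of tab-delimited inputs, plus `input_cols` /
#'     `output_cols`;
#'   * `frontier_scope`: `"per_year"` (default) or `"pooled"`;
#'   * `scheme`: `"tercile"` (default) or `"quartile"`;
#'   * `region_groups`: optional data frame `region_id`, `group` (enables
#'     the transition equations);
#'   * `states`: optional precomputed state panel (from
#'     [classify_states()]); lets downstream-only runs (e.g. `stages =
#'     "markov"`) start from saved upstream artifacts;
#'   * `stages`: subset of `c("dea", "states", "markov", "spatial",
#'     "transitions")` (default all feasible).
#' @param output_dir directory for the stage outputs (created if needed).
#' @return Invisibly, the manifest data frame; stage results are also
#'   returned in the `results` attribute.
#' @export
run_pipeline <- function(config, output_dir) {
  if (!is.null(config$synth) && !is.null(config$files)) {
    stop("exactly one data source: synth config or files")
  }
  if (is.null(config$synth) && is.null(config$files) &&
      is.null(config$states)) {
    stop("no data source specified")
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  scope <- config$frontier_scope %||% "per_year"
  scheme <- config$scheme %||% "tercile"
  stages <- config$stages %||%
    c("dea", "states", "markov", "spatial", "transitions")
  manifest <- list()
  results <- list()
  emit <- function(stage, name, tab) {
    path <- file.path(output_dir, paste0(name, ".tsv"))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, file = basename(path),
      md5 = unname(tools::md5sum(path)), n_rows = nrow(tab))
    path
  }

  # -- data ----------------------------------------------------------------
  weights <- NULL
  covs <- NULL
  if (!is.null(config$synth)) {
    sc <- config$synth
    weights <- generate_adjacency(sc)
    gen <- generate_panel(sc, weights = weights)
    panel <- gen$panel
    covs <- generate_covariates(sc, gen$truth)
    results$truth <- gen$truth
    emit("data", "panel", panel)
    emit("data", "adjacency", weights$edges)
    emit("data", "covariates", covs)
    emit("data", "latent_states", gen$truth$latent_states)
  } else if (is.null(config$files)) {
    panel <- NULL  # precomputed states only
  } else {
    fl <- config$files
    for (p in c(fl$panel, fl$adjacency, fl$covariates)) {
      if (!file.exists(p)) stop("input file not found: ", p)
    }
    panel <- read.delim(fl$panel)
    attr(panel, "input_cols") <- fl$input_cols
    attr(panel, "output_cols") <- fl$output_cols
    if (!is.null(fl$adjacency)) {
      weights <- spatial_weights(read.delim(fl$adjacency),
                                 regions = unique(panel$region_id))
    }
    if (!is.null(fl$covariates)) covs <- read.delim(fl$covariates)
  }
  results$panel <- panel
  if (!is.null(config$states)) results$states <- config$states

  # -- stages --------------------------------------------------------------
  if ("dea" %in% stages) {
    eff <- dea_score_panel(panel, frontier_scope = scope)
    results$efficiency <- eff
    emit("dea", "efficiency", eff)
  }
  if ("states" %in% stages) {
    if (is.null(results$efficiency)) stop("states stage needs the dea stage")
    th <- efficiency_thresholds(results$efficiency$pte, scheme = scheme)
    st <- classify_states(results$efficiency, th)
    results$thresholds <- th
    results$states <- st
    emit("states", "states", st)
    emit("states", "thresholds",
         data.frame(threshold = as.numeric(th), scheme = attr(th, "scheme")))
  }
  if ("markov" %in% stages) {
    if (is.null(results$states)) stop("markov stage needs the states stage")
    est <- estimate_transitions(results$states)
    sd_ <- stationary_distribution(est)
    results$transitions_estimate <- est
    results$stationary <- sd_
    emit("markov", "transition_counts", as.data.frame(est$counts))
    emit("markov", "transition_probabilities",
         as.data.frame(est$probabilities))
    emit("markov", "stationary",
         data.frame(state = seq_along(sd_$pi), pi = sd_$pi))
  }
  if ("spatial" %in% stages && !is.null(weights)) {
    if (is.null(results$states)) stop("spatial stage needs the states stage")
    lags <- spatial_lag(results$states, weights)
    ctx <- assign_contexts(lags)
    cond <- conditional_transitions(results$states, ctx)
    results$contexts <- ctx
    results$conditional <- cond
    emit("spatial", "contexts", ctx)
    for (nm in names(cond$by_context)) {
      emit("spatial", paste0("transition_", nm),
           as.data.frame(cond$by_context[[nm]]$probabilities))
    }
    if (length(cond$by_context) >= 2) {
      contrast <- context_contrast(cond)
      results$contrast <- contrast
      emit("spatial", "context_contrast", contrast$cells)
    }
  }
  if ("transitions" %in% stages && !is.null(covs) &&
      !is.null(config$region_groups)) {
    if (is.null(results$states)) {
      stop("transitions stage needs the states stage")
    }
    oc <- build_outcomes(results$states)
    for (side in c("upward", "downward")) {
      m <- fit_lpm(oc, covs, outcome = side,
                   region_groups = config$region_groups)
      results[[paste0("lpm_", side)]] <- m
      emit("transitions", paste0("lpm_", side),
           cbind(m$coefficients,
                 n_obs = m$n_obs, r_squared = m$r_squared))
    }
  }

  man <- do.call(rbind, manifest)
  jsonlite::write_json(man, file.path(output_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  attr(man, "results") <- results
  invisible(man)
}
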