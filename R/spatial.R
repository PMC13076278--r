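#' Undirected region adjacency weights
#'
#' Stores an undirected edge list between region ids plus the set of islands
#' (regions with no neighbours). Self-loops are dropped; duplicate /
#' reversed pairs are collapsed, so symmetry holds by construction.
#'
#' @param edges data frame or 2-column matrix of region-id pairs; `NULL` for
#'   an edgeless map.
#' @param regions optional full region-id vector; defaults to the ids seen
#'   in `edges`. Regions listed here but absent from every edge are islands.
#' @return Object of class `"spatial_weights"`: list with `edges`
#'   (data frame `from`, `to`), `regions`, `islands`.
#' @export
spatial_weights <- function(edges = NULL, regions = NULL) {
  if (is.null(edges) || !NROW(edges)) {
    edges <- data.frame(from = character(0), to = character(0))
  } else {
    edges <- as.data.frame(edges)[, 1:2]
    names(edges) <- c("from", "to")
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    edges <- edges[edges$from != edges$to, ]  # no self-loops
    key <- ifelse(edges$from < edges$to,
                  paste(edges$from, edges$to),
                  paste(edges$to, edges$from))
    edges <- edges[!duplicated(key), ]
    rownames(edges) <- NULL
  }
  seen <- unique(c(edges$from, edges$to))
  regions <- if (is.null(regions)) seen else as.character(regions)
  if (length(setdiff(seen, regions))) {
    stop("edge list mentions regions outside the region set")
  }
  structure(list(edges = edges, regions = regions,
                 islands = setdiff(regions, seen)),
            class = "spatial_weights")
}

#' Within-group "adjacency" for the same-region robustness scheme
#'
#' Replaces geographic contiguity by group membership: every pair of regions
#' in the same group is connected (self excluded). Feeding the result to
#' [spatial_lag()] makes a region's lag the mean state of its group
#' excluding itself.
#'
#' @param region_groups data frame with columns `region_id`, `group`.
#' @return A [spatial_weights()] object. Singleton groups become islands.
#' @export
same_region_weights <- function(region_groups) {
  stopifnot(all(c("region_id", "group") %in% names(region_groups)))
  sp <- split(as.character(region_groups$region_id), region_groups$group)
  ed <- do.call(rbind, lapply(sp, function(ids) {
    if (length(ids) < 2) return(NULL)
    t(utils::combn(ids, 2))
  }))
  spatial_weights(edges = ed, regions = region_groups$region_id)
}

neighbour_list <- function(weights) {
  nb <- lapply(setNames(vector("list", length(weights$regions)),
                        weights$regions), function(x) character(0))
  for (i in seq_len(nrow(weights$edges))) {
    f <- weights$edges$from[i]; t_ <- weights$edges$to[i]
    nb[[f]] <- c(nb[[f]], t_)
    nb[[t_]] <- c(nb[[t_]], f)
  }
  nb
}

#' Spatial lag of efficiency states
#'
#' For each region-year, the unweighted mean of the contemporaneous states
#' of the region's neighbours. Islands get `NA` lags and are excluded from
#' downstream conditioning (their count is reported via a message).
#'
#' @param states state panel from [classify_states()].
#' @param weights a [spatial_weights()] object covering every region in
#'   `states`.
#' @return Data frame (`region_id`, `year`, `lag_value`) carrying the
#'   states' `threshold_spec` attribute forward.
#' @export
spatial_lag <- function(states, weights) {
  missing_r <- setdiff(unique(states$region_id), weights$regions)
  if (length(missing_r)) {
    stop("region(s) absent from the weights: ",
         paste(missing_r, collapse = ", "))
  }
  nb <- neighbour_list(weights)
  out <- data.frame(region_id = states$region_id, year = states$year,
                    lag_value = NA_real_)
  for (yr in unique(states$year)) {
    sel <- states$year == yr
    st <- setNames(states$state[sel], states$region_id[sel])
    out$lag_value[sel] <- vapply(states$region_id[sel], function(r) {
      nn <- intersect(nb[[r]], names(st))
      if (!length(nn)) NA_real_ else mean(st[nn])
    }, numeric(1))
  }
  n_island <- sum(is.na(out$lag_value))
  if (n_island) {
    message(n_island, " island region-year(s) have undefined spatial lags")
  }
  attr(out, "threshold_spec") <- attr(states, "threshold_spec")
  out
}

#' Classify neighbourhood contexts from spatial lags
#'
#' Cuts the pooled defined lag values at their 33rd and 67th percentiles
#' (same linear-interpolation quantiles and lower-closed boundary rule as
#' the state classification) into neighbourhood contexts 1..3: low-, medium-
#' and high-efficiency environments.
#'
#' @param lags output of [spatial_lag()] (possibly computed with
#'   [same_region_weights()] for the same-region robustness scheme).
#' @return Data frame (`region_id`, `year`, `lag_value`, `context`) with a
#'   `context_thresholds` attribute; `context` is `NA` where the lag is
#'   undefined.
#' @export
assign_contexts <- function(lags) {
  v <- lags$lag_value[!is.na(lags$lag_value)]
  if (!length(v)) stop("no defined lag values")
  if (length(unique(v)) < 3) {
    warning("fewer than 3 distinct lag values; contexts are degenerate")
  }
  th <- unname(quantile(v, c(0.33, 0.67), type = 7, names = FALSE))
  out <- lags
  out$context <- ifelse(is.na(out$lag_value), NA_integer_,
                        findInterval(out$lag_value, th) + 1L)
  attr(out, "context_thresholds") <- th
  attr(out, "threshold_spec") <- attr(lags, "threshold_spec")
  out
}

#' Conditional (spatial Markov) transition matrices
#'
#' Splits the pooled one-step transitions by the neighbourhood context of
#' the origin observation: the transition from year `t` to `t+1` of region
#' `r` is assigned to the context of `(r, t)`. Returns one
#' [estimate_transitions()]-style estimate per context, plus the pooled
#' estimate over all transitions with a defined origin context (so the
#' per-context count matrices sum exactly to the pooled counts).
#'
#' @param states state panel from [classify_states()].
#' @param contexts context panel from [assign_contexts()].
#' @return Object of class `"conditional_transitions"`: list with
#'   `by_context` (named list of `"transition_estimate"`), `pooled`, and
#'   `n_dropped` (transitions with undefined origin context, excluded).
#' @export
conditional_transitions <- function(states, contexts) {
  spec <- attr(states, "threshold_spec")
  K <- if (!is.null(spec)) spec$n_states else max(states$state)
  pairs <- transition_pairs(states)
  key <- paste(contexts$region_id, contexts$year)
  ctx <- contexts$context[match(paste(pairs$region_id, pairs$year), key)]
  defined <- !is.na(ctx)
  n_dropped <- sum(!defined)
  if (n_dropped) {
    message(n_dropped, " transition(s) dropped: undefined origin context")
  }
  pairs <- pairs[defined, ]
  ctx <- ctx[defined]
  count_est <- function(pp) {
    tab <- table(factor(pp$state, levels = 1:K),
                 factor(pp$state_next, levels = 1:K))
    counts <- matrix(as.integer(tab), K, K)
    row_tot <- rowSums(counts)
    structure(list(counts = counts,
                   probabilities = counts / ifelse(row_tot > 0, row_tot,
                                                   NA_real_),
                   n_transitions = sum(counts),
                   undefined_rows = which(row_tot == 0),
                   n_states = K, threshold_spec = spec),
              class = "transition_estimate")
  }
  levs <- sort(unique(ctx))
  by_context <- lapply(levs, function(cc) count_est(pairs[ctx == cc, ]))
  names(by_context) <- paste0("context_", levs)
  structure(list(by_context = by_context, pooled = count_est(pairs),
                 n_dropped = n_dropped),
            class = "conditional_transitions")
}

#' Cross-context contrast of transition probabilities
#'
#' Long table of every transition-matrix cell by context, plus the
#' cross-context spread for the key cells p11, p12, p23, p33 (the cells the
#' spatial-conditioning hypothesis speaks to: retention at the bottom and
#' top, and upward mobility out of the low and medium states).
#'
#' @param cond a `"conditional_transitions"` object.
#' @return List with `cells` (data frame `from`, `to`, `context`,
#'   `probability`; undefined cells are `NA`, never zero-filled) and
#'   `key_cells` (wide data frame, one row per key cell, one column per
#'   context, plus `spread = max - min` over defined contexts).
#' @export
context_contrast <- function(cond) {
  if (length(cond$by_context) < 2) {
    stop("need at least 2 contexts to contrast")
  }
  K <- cond$pooled$n_states
  cells <- do.call(rbind, lapply(names(cond$by_context), function(nm) {
    P <- cond$by_context[[nm]]$probabilities
    data.frame(from = rep(1:K, K), to = rep(1:K, each = K),
               context = nm, probability = as.vector(P))
  }))
  key <- data.frame(from = c(1, 1, 2, K), to = c(1, 2, 3, K))
  key <- key[key$to <= K & key$from <= K, ]
  wide <- data.frame(cell = paste0("p", key$from, key$to))
  for (nm in names(cond$by_context)) {
    P <- cond$by_context[[nm]]$probabilities
    wide[[nm]] <- P[cbind(key$from, key$to)]
  }
  pm <- as.matrix(wide[, -1, drop = FALSE])
  wide$spread <- apply(pm, 1, function(z) {
    z <- z[!is.na(z)]
    if (length(z) < 2) NA_real_ else max(z) - min(z)
  })
  list(cells = cells, key_cells = wide)
}
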