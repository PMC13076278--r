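#' Pooled percentile thresholds for efficiency states
#'
#' Computes the cut points that discretize pooled efficiency scores into
#' relative states: the 33rd and 67th percentiles for the tercile scheme
#' (3 states), or the 25th/50th/75th for the quartile robustness scheme
#' (4 states). Quantiles use linear interpolation of the empirical
#' distribution (type 7, the common default).
#'
#' @param scores numeric vector of pooled efficiency scores (all region-year
#'   observations together).
#' @param scheme `"tercile"` or `"quartile"`.
#' @return Numeric threshold vector (nondecreasing) of class
#'   `"efficiency_thresholds"`, with attributes `scheme` and `n_states`.
#' @examples
#' efficiency_thresholds(seq(0.1, 1, by = 0.1))  # 0.397, 0.703
#' @export
efficiency_thresholds <- function(scores, scheme = c("tercile", "quartile")) {
  scheme <- match.arg(scheme)
  scores <- as.numeric(scores)
  if (!length(scores) || any(!is.finite(scores))) {
    stop("scores must be a non-empty finite numeric vector")
  }
  probs <- switch(scheme, tercile = c(0.33, 0.67),
                  quartile = c(0.25, 0.50, 0.75))
  k <- length(probs) + 1L
  if (length(unique(scores)) < k) {
    warning("fewer than ", k, " distinct scores; state classification ",
            "is degenerate")
  }
  th <- unname(quantile(scores, probs, type = 7, names = FALSE))
  structure(th, scheme = scheme, n_states = k,
            class = "efficiency_thresholds")
}

#' Classify efficiency scores into relative states
#'
#' Maps each region-year pure-technical-efficiency score to a discrete state
#' `1..K` using thresholds from [efficiency_thresholds()]. Intervals are
#' lower-closed: state 1 iff `pte < t1`; state `j` iff
#' `t_{j-1} <= pte < t_j`; state `K` iff `pte >= t_{K-1}`. The rule is
#' deterministic and monotone, and sends ties at the frontier (`pte = 1`
#' mass points) to the top state.
#'
#' @param scores_panel data frame with `region_id`, `year` and the score
#'   column (an efficiency panel from [dea_score_panel()], or any panel).
#' @param thresholds an `"efficiency_thresholds"` object computed on the
#'   pooled sample; plain numeric vectors are accepted.
#' @param score_col name of the score column; default `"pte"`.
#' @return Data frame (`region_id`, `year`, `state`) with attribute
#'   `threshold_spec` recording the thresholds, scheme and state count.
#' @export
classify_states <- function(scores_panel, thresholds, score_col = "pte") {
  req <- c("region_id", "year", score_col)
  miss <- setdiff(req, names(scores_panel))
  if (length(miss)) stop("panel lacks columns: ", paste(miss, collapse = ", "))
  x <- scores_panel[[score_col]]
  if (any(!is.finite(x)) || any(x <= 0 | x > 1 + 1e-9)) {
    stop("scores must lie in (0, 1]")
  }
  th <- as.numeric(thresholds)
  if (is.unsorted(th)) stop("thresholds must be nondecreasing")
  k <- length(th) + 1L
  state <- findInterval(x, th) + 1L  # lower-closed: x >= t_j counts t_j
  out <- data.frame(region_id = scores_panel$region_id,
                    year = scores_panel$year, state = state)
  attr(out, "threshold_spec") <- list(
    thresholds = th,
    scheme = attr(thresholds, "scheme") %||% "custom",
    n_states = k
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
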