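#' Upward / downward mobility indicators from state sequences
#'
#' Builds, for every consecutive-year pair within a region, the indicators
#' `upward = 1{S_{t+1} > S_t}` and `downward = 1{S_{t+1} < S_t}`, together
#' with the at-risk flags used by the transition equations: an observation
#' is at risk of an upward move iff its origin state is below the top state,
#' and at risk of a downward move iff above the bottom state.
#'
#' @param states state panel from [classify_states()].
#' @return Data frame (`region_id`, `year`, `state`, `state_next`,
#'   `upward`, `downward`, `at_risk_up`, `at_risk_down`), one row per
#'   origin-year transition pair.
#' @export
build_outcomes <- function(states) {
  spec <- attr(states, "threshold_spec")
  K <- if (!is.null(spec)) spec$n_states else max(states$state)
  pairs <- transition_pairs(states)
  pairs$upward <- as.integer(pairs$state_next > pairs$state)
  pairs$downward <- as.integer(pairs$state_next < pairs$state)
  pairs$at_risk_up <- pairs$state < K
  pairs$at_risk_down <- pairs$state > 1
  pairs
}

#' Linear-probability transition equation
#'
#' Least-squares fit of an upward (or downward) mobility indicator on
#' resource-structure covariates measured at the origin year, with year and
#' region-group (or province) fixed-effect blocks, on the at-risk sample
#' (top-state origins are excluded from the upward model, bottom-state
#' origins from the downward model). Standard errors are cluster-robust by
#' region with CR1 small-sample scaling
#' `G/(G-1) * (N-1)/(N-k)`.
#'
#' @param outcomes output of [build_outcomes()].
#' @param covariates data frame with `region_id`, `year` and the covariate
#'   columns, matched to outcomes at the origin year.
#' @param outcome `"upward"` or `"downward"`.
#' @param covariate_names covariate columns to include; default the four
#'   resource-structure covariates.
#' @param region_groups data frame `region_id`, `group`; required when
#'   `fe_region = "group"` (the default).
#' @param fe_region `"group"` for region-group dummies (the default; four
#'   broad groups keep the design light relative to ~30 clusters) or
#'   `"province"` for one dummy per region.
#' @return Object of class `"transition_lpm"`: list with `coefficients`
#'   (covariate rows: estimate, cluster SE, t, p, stars), `n_obs`,
#'   `r_squared`, `n_clusters`, `outcome`, `vcov` (full CR1 matrix), `fit`
#'   (the underlying `lm`), `n_dropped_missing`.
#' @export
fit_lpm <- function(outcomes, covariates, outcome = c("upward", "downward"),
                    covariate_names = c("doctor_nurse_ratio", "staff_per_10k",
                                        "beds_per_staff", "ln_gdp_pc"),
                    region_groups = NULL,
                    fe_region = c("group", "province")) {
  outcome <- match.arg(outcome)
  fe_region <- match.arg(fe_region)
  miss <- setdiff(c("region_id", "year", covariate_names), names(covariates))
  if (length(miss)) stop("covariates lack columns: ",
                         paste(miss, collapse = ", "))
  d <- merge(outcomes, covariates, by = c("region_id", "year"))
  d <- d[if (outcome == "upward") d$at_risk_up else d$at_risk_down, ]
  keep <- complete.cases(d[covariate_names])
  n_dropped <- sum(!keep)
  if (n_dropped) message(n_dropped, " row(s) dropped for missing covariates")
  d <- d[keep, ]
  if (fe_region == "group") {
    if (is.null(region_groups)) {
      stop("region_groups required for region-group fixed effects")
    }
    d$fe_block <- region_groups$group[match(d$region_id,
                                            region_groups$region_id)]
    if (anyNA(d$fe_block)) stop("region(s) missing from region_groups")
  } else {
    d$fe_block <- d$region_id
  }
  d$y <- d[[outcome]]
  d$year_f <- factor(d$year)
  d$fe_block <- factor(d$fe_block)

  G <- length(unique(d$region_id))
  if (G < 2) stop("need at least 2 clusters")

  rhs <- c(covariate_names,
           if (nlevels(d$year_f) > 1) "year_f",
           if (nlevels(d$fe_block) > 1) "fe_block")
  f <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  fit <- lm(f, data = d)
  if (anyNA(coef(fit))) {
    stop("rank-deficient design; collinear term(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  V <- cluster_vcov_cr1(fit, d$region_id)
  est <- coef(fit)[covariate_names]
  se <- sqrt(diag(V))[covariate_names]
  tval <- est / se
  pval <- 2 * pt(abs(tval), df = G - 1, lower.tail = FALSE)
  stars <- vapply(pval, function(p) {
    if (!is.finite(p)) "" else if (p < 0.01) "***" else if (p < 0.05) "**"
    else if (p < 0.1) "*" else ""
  }, character(1))
  structure(list(
    coefficients = data.frame(term = covariate_names, estimate = unname(est),
                              se = unname(se), t = unname(tval),
                              p = unname(pval), stars = stars,
                              row.names = NULL),
    n_obs = nrow(d),
    r_squared = {
      r2 <- summary(fit)$r.squared
      if (is.finite(r2)) r2 else 0  # constant outcome: no variance to explain
    },
    n_clusters = G, outcome = outcome, vcov = V, fit = fit,
    n_dropped_missing = n_dropped
  ), class = "transition_lpm")
}

# CR1 cluster-robust covariance: (X'X)^-1 [sum_g X_g'e_g e_g'X_g] (X'X)^-1
# scaled by G/(G-1) * (N-1)/(N-k)
cluster_vcov_cr1 <- function(fit, cluster) {
  X <- model.matrix(fit)
  e <- resid(fit)
  N <- nrow(X); k <- ncol(X); G <- length(unique(cluster))
  bread <- solve(crossprod(X))
  scores <- rowsum(X * e, group = cluster)
  meat <- crossprod(as.matrix(scores))
  adj <- G / (G - 1) * (N - 1) / (N - k)
  V <- adj * bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' @export
print.transition_lpm <- function(x, digits = 4, ...) {
  cat(sprintf("Linear probability model: %s transition (n = %d, G = %d, R2 = %.4f)\n",
              x$outcome, x$n_obs, x$n_clusters, x$r_squared))
  co <- x$coefficients
  for (i in seq_len(nrow(co))) {
    cat(sprintf("  %-18s % .4f%s (%.4f)\n", co$term[i], co$estimate[i],
                formatC(co$stars[i], width = -3), co$se[i]))
  }
  invisible(x)
}
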