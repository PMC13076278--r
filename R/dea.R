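#' Input-oriented radial DEA efficiency for one unit
#'
#' Solves the envelopment linear program for the evaluated decision-making
#' unit: minimize theta subject to `X'lambda <= theta * x_o` (componentwise),
#' `Y'lambda >= y_o`, `lambda >= 0`, and `sum(lambda) == 1` under variable
#' returns to scale (BCC). Dropping the convexity constraint gives the
#' constant-returns CCR score. Theta is the maximal equiproportionate input
#' contraction feasible at the unit's output level, so `theta` lies in (0, 1]
#' whenever the unit itself belongs to the reference set.
#'
#' @param inputs n x m matrix of strictly positive input quantities, one row
#'   per unit.
#' @param outputs n x s matrix of strictly positive output quantities.
#' @param unit index (row) of the evaluated unit.
#' @param rts returns to scale: `"vrs"` (BCC, convexity constraint) or
#'   `"crs"` (CCR).
#' @param tol numerical tolerance for clipping theta into (0, 1].
#' @return List with `theta` (efficiency score), `lambda` (intensity weights
#'   over reference units; any optimal vertex when the optimum is degenerate),
#'   `rts` and `unit`.
#' @examples
#' x <- matrix(c(1, 2), ncol = 1); y <- matrix(c(1, 1), ncol = 1)
#' dea_solve(x, y, unit = 2, rts = "vrs")$theta  # 0.5: contract onto unit 1
#' @export
dea_solve <- function(inputs, outputs, unit, rts = c("vrs", "crs"),
                      tol = 1e-9) {
  rts <- match.arg(rts)
  inputs <- as.matrix(inputs)
  outputs <- as.matrix(outputs)
  n <- nrow(inputs)
  if (nrow(outputs) != n) stop("inputs and outputs must have the same rows")
  if (any(!is.finite(inputs)) || any(!is.finite(outputs)) ||
      any(inputs <= 0) || any(outputs <= 0)) {
    stop("all input and output quantities must be strictly positive")
  }
  if (!(unit %in% seq_len(n))) stop("evaluated unit out of range")
  m <- ncol(inputs)
  s <- ncol(outputs)

  # radial DEA is invariant to positive column rescaling; normalising each
  # column by its maximum conditions the tableau without changing theta or
  # lambda
  inputs <- sweep(inputs, 2, apply(inputs, 2, max), "/")
  outputs <- sweep(outputs, 2, apply(outputs, 2, max), "/")

  # standard form: z = (theta, lambda_1..n, input slacks, output surpluses)
  nz <- 1 + n + m + s
  A <- matrix(0, m + s + (rts == "vrs"), nz)
  b <- numeric(nrow(A))
  A[seq_len(m), 1] <- -inputs[unit, ]             # X'lam - theta x_o + s = 0
  A[seq_len(m), 1 + seq_len(n)] <- t(inputs)
  A[seq_len(m), 1 + n + seq_len(m)] <- diag(m)
  A[m + seq_len(s), 1 + seq_len(n)] <- t(outputs) # Y'lam - t = y_o
  A[m + seq_len(s), 1 + n + m + seq_len(s)] <- -diag(s)
  b[m + seq_len(s)] <- outputs[unit, ]
  if (rts == "vrs") {
    A[m + s + 1, 1 + seq_len(n)] <- 1             # sum(lambda) = 1
    b[m + s + 1] <- 1
  }
  sol <- lp_simplex(c(1, rep(0, nz - 1)), A, b)
  if (sol$status != "optimal") {
    stop("envelopment LP ", sol$status, " (self-including reference set ",
         "should always be feasible)")
  }
  theta <- sol$value
  if (theta > 1 + 1e-6 || theta <= -1e-6) {
    stop("LP returned theta = ", theta, ", outside (0, 1]")
  }
  theta <- min(max(theta, tol), 1)
  list(theta = theta, lambda = sol$z[1 + seq_len(n)], rts = rts, unit = unit)
}

#' Scale-efficiency decomposition
#'
#' Scale efficiency is the ratio of the constant-returns (CCR) score to the
#' variable-returns (BCC) score, `se = te / pte`: the distance between the
#' CRS and VRS frontiers. Vectorized.
#'
#' @param pte BCC (pure technical) efficiency in (0, 1].
#' @param te CCR (overall technical) efficiency in (0, 1]; must not exceed
#'   `pte` beyond `tol` (the CRS frontier envelops the VRS frontier).
#' @param tol tolerance for the envelopment check and the final clip to 1.
#' @return Scale efficiency in (0, 1].
#' @export
dea_decompose <- function(pte, te, tol = 1e-7) {
  if (length(pte) != length(te)) stop("pte and te lengths differ")
  if (any(pte <= 0 | pte > 1 + tol) || any(te <= 0 | te > 1 + tol)) {
    stop("efficiency scores must lie in (0, 1]")
  }
  bad <- te > pte + tol
  if (any(bad)) {
    stop("te > pte beyond tolerance at position(s) ",
         paste(which(bad), collapse = ", "),
         " -- inconsistent LP solutions (CRS must envelop VRS)")
  }
  pmin(te / pte, 1)
}

#' DEA efficiency scores for a region-year panel
#'
#' Computes the BCC (pure technical, `pte`), CCR (overall technical, `te`)
#' and scale (`se = te/pte`) efficiency of every region-year observation.
#' With `frontier_scope = "per_year"` each observation is evaluated against
#' the cross-section of its own year (contemporaneous frontier, the default);
#' with `"pooled"` against all region-years at once.
#'
#' @param panel data frame with columns `region_id`, `year`, and the input /
#'   output quantity columns. `(region_id, year)` pairs must be unique and
#'   all quantities strictly positive.
#' @param frontier_scope `"per_year"` or `"pooled"`.
#' @param input_cols,output_cols character vectors naming the input and
#'   output columns. Default to the `input_cols` / `output_cols` attributes
#'   that [generate_panel()] sets.
#' @return Data frame (`region_id`, `year`, `pte`, `te`, `se`), one row per
#'   panel observation.
#' @export
dea_score_panel <- function(panel,
                            frontier_scope = c("per_year", "pooled"),
                            input_cols = attr(panel, "input_cols"),
                            output_cols = attr(panel, "output_cols")) {
  frontier_scope <- match.arg(frontier_scope)
  if (is.null(input_cols) || is.null(output_cols)) {
    stop("input_cols / output_cols not given and not stored on the panel")
  }
  req <- c("region_id", "year", input_cols, output_cols)
  miss <- setdiff(req, names(panel))
  if (length(miss)) stop("panel lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(panel[c("region_id", "year")])) {
    stop("(region_id, year) pairs must be unique")
  }
  X <- as.matrix(panel[input_cols])
  Y <- as.matrix(panel[output_cols])
  if (any(X <= 0) || any(Y <= 0)) stop("quantities must be strictly positive")

  score_block <- function(rows) {
    xb <- X[rows, , drop = FALSE]
    yb <- Y[rows, , drop = FALSE]
    nb <- length(rows)
    pte <- te <- numeric(nb)
    for (i in seq_len(nb)) {
      pte[i] <- dea_solve(xb, yb, i, rts = "vrs")$theta
      te[i] <- dea_solve(xb, yb, i, rts = "crs")$theta
    }
    # tiny solver noise can put te a hair above pte when both are ~1;
    # genuine violations (> 1e-9) are left for dea_decompose to flag
    snap <- te > pte & (te - pte) < 1e-9
    te[snap] <- pte[snap]
    cbind(pte = pte, te = te)
  }

  out <- data.frame(region_id = panel$region_id, year = panel$year,
                    pte = NA_real_, te = NA_real_)
  if (frontier_scope == "pooled") {
    sc <- score_block(seq_len(nrow(panel)))
    out$pte <- sc[, "pte"]; out$te <- sc[, "te"]
  } else {
    for (yr in unique(panel$year)) {
      rows <- which(panel$year == yr)
      if (!length(rows)) {
        warning("empty cross-section for year ", yr, "; skipped")
        next
      }
      sc <- score_block(rows)
      out$pte[rows] <- sc[, "pte"]; out$te[rows] <- sc[, "te"]
    }
  }
  out$se <- dea_decompose(out$pte, out$te)
  out
}
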