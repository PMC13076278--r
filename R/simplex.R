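# Dense two-phase primal simplex for the envelopment LPs.
#
# Solves  min c'z  s.t.  A z = b, z >= 0  (b >= 0 required; callers arrange
# signs). Bland's anti-cycling rule guarantees termination; the tableaux
# here are tiny (m+s+1 rows), so the dense textbook method is both robust
# and fast. Returns list(z, value, status) with status one of "optimal",
# "infeasible", "unbounded".

lp_simplex <- function(cvec, A, b, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  if (length(b) != m || length(cvec) != n) stop("dimension mismatch")
  if (any(b < 0)) stop("b must be nonnegative in standard form")

  # phase 1: artificial basis
  Tb <- cbind(A, diag(m), b)            # tableau: [A | I | b]
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  res <- simplex_iterate(Tb, basis, cost1, ncol(Tb) - 1L, tol)
  Tb <- res$Tb; basis <- res$basis
  phase1_val <- sum(Tb[, ncol(Tb)] * (basis > n))
  if (phase1_val > 1e-7) {
    return(list(z = NULL, value = NA_real_, status = "infeasible"))
  }
  # drive any zero-level artificials out of the basis where possible
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      piv <- which(abs(Tb[i, seq_len(n)]) > tol)
      if (length(piv)) {
        Tb <- pivot_tableau(Tb, i, piv[1])
        basis[i] <- piv[1]
      }
    }
  }
  keep_rows <- basis <= n
  Tb <- Tb[keep_rows, , drop = FALSE]   # redundant rows (still artificial)
  basis <- basis[keep_rows]
  Tb <- Tb[, c(seq_len(n), ncol(Tb)), drop = FALSE]

  # phase 2
  res <- simplex_iterate(Tb, basis, cvec, n, tol)
  if (res$status == "unbounded") {
    return(list(z = NULL, value = NA_real_, status = "unbounded"))
  }
  Tb <- res$Tb; basis <- res$basis
  z <- numeric(n)
  z[basis] <- Tb[, ncol(Tb)]
  list(z = z, value = sum(cvec * z), status = "optimal")
}

simplex_iterate <- function(Tb, basis, cost, nvar, tol) {
  iter <- 0L
  repeat {
    iter <- iter + 1L
    rhs_col <- ncol(Tb)
    # reduced costs for the first nvar structural columns
    cb <- cost[basis]
    red <- cost[seq_len(nvar)] -
      drop(crossprod(Tb[, seq_len(nvar), drop = FALSE], cb))
    red[basis[basis <= nvar]] <- 0
    enter <- which(red < -tol)
    if (!length(enter)) return(list(Tb = Tb, basis = basis, status = "optimal"))
    # Dantzig rule for speed, Bland's rule after a while to rule out cycling
    j <- if (iter <= 500L) enter[which.min(red[enter])] else min(enter)
    col <- Tb[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(Tb = Tb, basis = basis, status = "unbounded"))
    ratio <- Tb[pos, rhs_col] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    i <- if (iter <= 500L) cand[which.max(col[cand])] else
      cand[which.min(basis[cand])]
    Tb <- pivot_tableau(Tb, i, j)
    basis[i] <- j
    if (iter > 100000L) stop("simplex iteration limit reached")
  }
}

pivot_tableau <- function(Tb, i, j) {
  Tb[i, ] <- Tb[i, ] / Tb[i, j]
  other <- setdiff(seq_len(nrow(Tb)), i)
  Tb[other, ] <- Tb[other, , drop = FALSE] -
    outer(Tb[other, j], Tb[i, ])
  Tb[, j] <- 0; Tb[i, j] <- 1
  Tb
}
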