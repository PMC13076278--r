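# Independent bisection-on-theta oracle for the input-oriented envelopment
# problem. Feasibility of {lambda >= 0 : X'lam <= theta x_o, Y'lam >= y_o,
# (sum lam = 1)} at each candidate theta is decided by a phase-I linear
# program (minimize artificial variables) solved with pracma::linprog -- a
# solver path entirely separate from the package's own simplex.

oracle_feasible <- function(X, Y, unit, theta, rts) {
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  # variables: lambda (n), output artificials (s), [vrs artificials a+, a-]
  nv <- n + s + if (rts == "vrs") 2 else 0
  cc <- c(rep(0, n), rep(1, s), if (rts == "vrs") c(1, 1))
  A <- cbind(t(X), matrix(0, m, nv - n))            # X'lam <= theta x_o
  b <- theta * X[unit, ]
  A <- rbind(A, cbind(-t(Y), -diag(s),
                      matrix(0, s, nv - n - s)))    # Y'lam + a >= y_o
  b <- c(b, -Y[unit, ])
  Aeq <- NULL; beq <- NULL
  if (rts == "vrs") {
    Aeq <- matrix(c(rep(1, n), rep(0, s), 1, -1), 1)
    beq <- 1
  }
  # pracma's simplex breaks pivot ties at random, so a single call can fail
  # spuriously on a feasible system; a success (artificials ~ 0) is
  # trustworthy, a failure is retried with fresh random pivots
  for (attempt in 1:8) {
    res <- tryCatch(
      suppressWarnings(pracma::linprog(cc, A = A, b = b, Aeq = Aeq,
                                       beq = beq, maxiter = 2000,
                                       maximize = FALSE)),
      error = function(e) NULL)
    if (!is.null(res) && isTRUE(res$errno == 1)) return(isTRUE(res$fval < 1e-9))
  }
  FALSE
}

dea_oracle <- function(X, Y, unit, rts, tol = 1e-8) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  # condition like any radial-DEA implementation may: column normalisation
  X <- sweep(X, 2, apply(X, 2, max), "/")
  Y <- sweep(Y, 2, apply(Y, 2, max), "/")
  if (!oracle_feasible(X, Y, unit, 1, rts)) {
    stop("oracle: theta = 1 infeasible; self-inclusion violated")
  }
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (oracle_feasible(X, Y, unit, mid, rts)) hi <- mid else lo <- mid
  }
  hi
}
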