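#' Solve a bounded linear program
#'
#' Maximizes \code{obj \%*\% x} subject to \code{A x = b} and
#' \code{lower <= x <= upper}, using the package's dense bounded-variable
#' two-phase simplex. Infinite bounds are clamped to \code{±big} before the
#' solve; flux balance problems are naturally bounded so this is harmless.
#'
#' This is the numerical core behind [solve_fba()]; it is exported mainly so
#' that tests can exercise it against independent oracles.
#'
#' @param obj numeric objective coefficients (length = number of columns).
#' @param A constraint matrix (dense or `Matrix` sparse), rows are equalities.
#' @param b right-hand side (defaults to zeros).
#' @param lower,upper variable bounds, recycled to length `ncol(A)`.
#' @param big finite stand-in for infinite bounds.
#' @return list with `status` ("optimal", "infeasible", "unbounded"),
#'   `objective`, and `x` (the primal solution, `NA` unless optimal).
#' @export
solve_lp <- function(obj, A, b = NULL, lower = -Inf, upper = Inf, big = 1e6) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  n <- ncol(A)
  m <- nrow(A)
  if (is.null(b)) b <- numeric(m)
  lower <- rep_len(as.numeric(lower), n)
  upper <- rep_len(as.numeric(upper), n)
  lower[lower < -big] <- -big
  upper[upper > big] <- big
  if (any(lower > upper)) {
    return(list(status = "infeasible", objective = 0, x = rep(NA_real_, n)))
  }
  res <- .simplex_lp(A, as.numeric(b), rep_len(as.numeric(obj), n),
                     lower, upper)
  if (res$status == "maxit") {
    stop("LP solver hit its iteration limit (", m, " x ", n, " problem)")
  }
  if (res$status != "optimal") res$x <- rep(NA_real_, n)
  res[c("status", "objective", "x")]
}
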