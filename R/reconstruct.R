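## Reconstructing the unknown 2x2 cells of a published signal row.
##
## Published disproportionality tables print, per event, the case count `a`
## and the point estimates ROR, PRR and EBGM -- but not the other three
## cells.  Those three point-estimate equations in the three unknowns
## (b, c, d) can be solved numerically, after which any derived quantity
## (e.g. the Wald CI bounds) is recomputable and checkable against the
## published interval.

#' Solve a 2x2 table's hidden cells from published point estimates
#'
#' Finds `b, c, d > 0` satisfying `ror = ad/(bc)`,
#' `prr = a(c+d)/(c(a+b))` and `ebgm = aN/((a+b)(a+c))` with
#' `N = a+b+c+d`, by damped Newton iteration on `log(b), log(c), log(d)`
#' (the system is smooth and well-conditioned in log space; positivity is
#' automatic).
#'
#' @param a known case count.
#' @param ror,prr,ebgm published point estimates.
#' @param init starting values for `c(b, c, d)`.
#' @param tol convergence tolerance on the max absolute log-scale residual.
#' @param max_iter iteration cap.
#' @return named numeric vector `c(b, c, d)`; error if no convergence.
#' @export
solve_cells_from_stats <- function(a, ror, prr, ebgm,
                                   init = c(b = 10 * a, c = 10 * a,
                                            d = 1000 * a),
                                   tol = 1e-10, max_iter = 200L) {
  stopifnot(a > 0, ror > 0, prr > 0, ebgm > 0)
  resid <- function(x) {
    b <- exp(x[[1]]); c <- exp(x[[2]]); d <- exp(x[[3]])
    N <- a + b + c + d
    c(log(a * d / (b * c)) - log(ror),
      log(a * (c + d) / (c * (a + b))) - log(prr),
      log(a * N / ((a + b) * (a + c))) - log(ebgm))
  }
  x <- log(pmax(init, 1e-6))
  for (iter in seq_len(max_iter)) {
    fx <- resid(x)
    if (max(abs(fx)) < tol)
      return(c(b = exp(x[[1]]), c = exp(x[[2]]), d = exp(x[[3]])))
    J <- matrix(0, 3, 3)
    h <- 1e-7
    for (j in 1:3) {
      xp <- x; xp[[j]] <- xp[[j]] + h
      J[, j] <- (resid(xp) - fx) / h
    }
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step)) data_error("solve_cells_from_stats: singular Jacobian")
    # damp to keep the iterate in a sane region
    lim <- max(abs(step))
    if (lim > 5) step <- step * (5 / lim)
    x <- x - step
  }
  data_error("solve_cells_from_stats: no convergence")
}
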