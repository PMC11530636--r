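#' Mesh-refinement study container
#'
#' Pairs of element base size and scalar functional value for a grid
#' convergence analysis. Sizes must be strictly decreasing (coarse to fine);
#' refinement ratios outside the 1.25-2 band recommended by the NPARC
#' verification guidelines raise a warning, not an error.
#'
#' @param h element base sizes, strictly decreasing.
#' @param f functional values at each size.
#' @param Fs safety factor for the GCI (default 1.25, the three-or-more-grid
#'   convention).
#' @return object of class `mesh_study`.
#' @export
mesh_study <- function(h, f, Fs = 1.25) {
  if (length(h) != length(f)) stopf("'h' and 'f' must have the same length")
  if (length(h) < 2) stopf("need at least two grids")
  if (any(diff(h) >= 0)) stopf("'h' must be strictly decreasing (coarse to fine)")
  r <- h[-length(h)] / h[-1]
  if (any(r < 1.25 | r > 2))
    warning("refinement ratio(s) outside the recommended 1.25-2 band: ",
            paste(sprintf("%.3g", r), collapse = ", "))
  structure(list(h = h, f = f, r = r, Fs = Fs), class = "mesh_study")
}

#' Observed order of grid convergence
#'
#' For exactly three grids with a common refinement ratio r the closed form
#' p = ln((f3 - f2)/(f2 - f1)) / ln r is used (1 = finest). Otherwise
#' (f_exact, C, p) are fitted jointly by least squares on the model
#' f(h) = f_exact + C h^p. Non-monotone (oscillatory) differences are an
#' error: no order is returned.
#'
#' @param study a [mesh_study()] with at least three grids.
#' @return observed order p.
#' @export
fit_order <- function(study) {
  h <- study$h; f <- study$f
  if (length(h) < 3) stopf("order fitting needs at least three grids")
  d <- diff(f)   # coarse-to-fine differences
  if (any(d == 0) || length(unique(sign(d))) != 1)
    stopf("oscillatory convergence: functional differences change sign, no order returned")
  r <- study$r
  if (length(h) == 3 && abs(r[1] - r[2]) < 1e-9) {
    # f ordering is coarse (index 1) to fine (index 3)
    return(log((f[1] - f[2]) / (f[2] - f[3])) / log(r[1]))
  }
  # joint least squares for (f_exact, C, p): for fixed p the model is linear
  obj <- function(p) {
    X <- cbind(1, h^p)
    res <- stats::lm.fit(X, f)$residuals
    sum(res^2)
  }
  opt <- stats::optimize(obj, interval = c(0.05, 10), tol = 1e-10)
  opt$minimum
}

#' Grid Convergence Index
#'
#' GCI = Fs |(f_coarse - f_fine)/f_fine| / (r^p - 1) x 100 (percent):
#' a Richardson-extrapolation-based bound on the discretization error of the
#' fine-grid solution.
#'
#' @param f_fine,f_coarse functional values on the fine and coarse grids.
#' @param r refinement ratio (> 1).
#' @param p observed order of convergence (> 0).
#' @param Fs safety factor (default 1.25).
#' @return GCI in percent.
#' @export
gci <- function(f_fine, f_coarse, r, p, Fs = 1.25) {
  if (r <= 1) stopf("'r' must be > 1")
  if (p <= 0) stopf("'p' must be > 0")
  if (f_fine == 0) stopf("'f_fine' must be nonzero (relative error undefined)")
  Fs * abs((f_coarse - f_fine) / f_fine) / (r^p - 1) * 100
}

#' Asymptotic-range ratio
#'
#' GCI_23 / (r^p GCI_12) for consecutive grid pairs (1 = finest): values
#' near one indicate the solutions lie in the asymptotic range of
#' convergence.
#'
#' @param gci_12 GCI of the fine pair.
#' @param gci_23 GCI of the coarse pair.
#' @param r refinement ratio.
#' @param p observed order.
#' @return the ratio.
#' @export
asymptotic_ratio <- function(gci_12, gci_23, r, p) {
  if (gci_12 == 0) stopf("'gci_12' is zero: ratio undefined")
  gci_23 / (r^p * gci_12)
}

#' Full grid-convergence report
#'
#' Computes the observed order, per-pair GCIs, asymptotic ratios, and the
#' Richardson-extrapolated functional, and (when a benchmark value is given)
#' the relative error of the finest grid against it.
#'
#' @param study a [mesh_study()] with >= 3 grids.
#' @param benchmark optional very-fine-grid benchmark functional.
#' @return list with `p`, `gci` (percent, per consecutive pair, fine pair
#'   first), `asymptotic_ratio`, `f_extrapolated`, and
#'   `benchmark_error_pct` when a benchmark is supplied.
#' @export
gci_report <- function(study, benchmark = NULL) {
  p <- fit_order(study)
  h <- study$h; f <- study$f; n <- length(h)
  # index pairs fine-first: (n, n-1), (n-1, n-2), ...
  gcis <- numeric(n - 1); rs <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    f_fine <- f[n - k + 1]; f_coarse <- f[n - k]
    rs[k] <- h[n - k] / h[n - k + 1]
    gcis[k] <- gci(f_fine, f_coarse, rs[k], p, study$Fs)
  }
  ar <- if (n >= 3)
    vapply(seq_len(n - 2),
           function(k) asymptotic_ratio(gcis[k], gcis[k + 1], rs[k], p),
           numeric(1))
  else numeric(0)
  f_ex <- f[n] + (f[n] - f[n - 1]) / (rs[1]^p - 1)
  out <- list(p = p, gci = gcis, refinement_ratios = rs,
              asymptotic_ratio = ar, f_extrapolated = f_ex)
  if (!is.null(benchmark))
    out$benchmark_error_pct <- abs(f[n] - benchmark) / abs(benchmark) * 100
  out
}
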