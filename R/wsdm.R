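#' Symbolic transformation of a time series
#'
#' Encodes the local shape of a signal as a binary symbol string: symbol i is
#' `"+"` when the series increases from point i to point i + 1 and `"-"`
#' otherwise. Ties (no change) map to `"-"`, i.e. non-increase; any fixed,
#' documented tie rule preserves determinism and this one is used throughout.
#'
#' @param x Numeric series of length >= 2 with finite values.
#' @return Character vector of `"+"`/`"-"` symbols, length `length(x) - 1`.
#' @seealso [symbolic_weight()], [wsdm()]
#' @export
#' @examples
#' symbolize(c(1, 2, 3, 2))  # "+" "+" "-"
symbolize <- function(x) {
  if (!is.numeric(x) || length(x) < 2L)
    stop("'x' must be a numeric series of length >= 2")
  if (!all(is.finite(x))) stop("'x' must contain only finite values")
  ifelse(diff(x) > 0, "+", "-")
}

#' Symbolic similarity weight between two symbol strings
#'
#' One minus the normalized Hamming distance between two equal-length symbol
#' strings: 1 for identical strings (maximal similarity), 0 for strings that
#' disagree at every position (minimal similarity).
#'
#' @param a,b Character vectors of symbols of equal length >= 1.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' symbolic_weight(c("+", "+", "-", "-"), c("+", "-", "-", "-"))  # 0.75
symbolic_weight <- function(a, b) {
  if (length(a) != length(b)) stop("symbol sequences must have equal length")
  if (length(a) < 1L) stop("symbol sequences must have length >= 1")
  1 - sum(a != b) / length(a)
}

#' Pseudo-observations (rank transform)
#'
#' Maps a sample to ranks/n with average ranks for ties, the grid on which the
#' empirical copula is evaluated. The output is invariant under any strictly
#' increasing transform of the input, which is what makes copula-based
#' dependence measures insensitive to the marginal distributions.
#'
#' @param x Numeric vector with finite values.
#' @return Numeric vector of pseudo-observations in (0, 1\].
#' @export
pseudo_observations <- function(x) {
  if (!is.numeric(x)) stop("'x' must be numeric")
  if (!all(is.finite(x))) stop("'x' must contain only finite values")
  rank(x, ties.method = "average") / length(x)
}

#' Hoeffding's phi-square between two series
#'
#' Empirical estimate of the normalized squared L2 distance between the
#' copula of (x, y) and the independence (product) copula:
#' \deqn{\hat\Phi^2 = 90 \cdot \frac{1}{n^2} \sum_{i=1}^n \sum_{j=1}^n
#'   \left[\hat C(i/n, j/n) - \frac{i}{n}\frac{j}{n}\right]^2,}
#' where \eqn{\hat C(u, v) = \frac1n \#\{k : U_k \le u, V_k \le v\}} is the
#' empirical copula on the pseudo-observations. The constant 90 (see [H2])
#' normalizes the comonotone case to 1, so the estimate is near 0 under
#' independence and near 1 under perfect monotone dependence (increasing or
#' decreasing). Being rank-based, the estimate is exactly invariant under
#' strictly increasing marginal transforms. Under independence it carries a
#' positive small-sample bias of order 1/n.
#'
#' @param x,y Numeric series of equal length n >= 8.
#' @return A non-negative number, close to \[0, 1\].
#' @references Hoeffding's phi-square for copulas; empirical estimator via the
#'   copula step function on the rank grid.
#' @export
hoeffding_phi2 <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 8L) stop("need at least 8 observations")
  u <- pseudo_observations(x)
  v <- pseudo_observations(y)
  H2 * .phi2_grid_cpp(u, v)
}

#' Weighted Symbolic Dependence Metric
#'
#' The wSDM between two series is the product of a copula-based dependence
#' factor and a symbolic similarity weight:
#' \deqn{wSDM(x, y) = sw(\hat X, \hat Y) \cdot I(x, y),}
#' where \eqn{\hat X, \hat Y} are the increase/decrease symbol strings of the
#' two series, sw is one minus their normalized Hamming distance, and the
#' dependence factor I is Hoeffding's phi-square (default) or its square
#' root. The weight makes the metric sensitive to the sign and local shape of
#' the coupling: two perfectly anticorrelated series have phi-square near 1
#' but symbolic weight 0, hence wSDM 0.
#'
#' @param x,y Numeric series of equal length n >= 8.
#' @param factor Which copula factor to multiply by the symbolic weight:
#'   `"phi2"` (Hoeffding's phi-square, default) or `"phi"` (its square root).
#' @return An object of class `"wsdm"`: a list with elements `phi2`, `sw`,
#'   `wsdm`, `n` and `factor`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(100)
#' wsdm(x, x + rnorm(100, sd = 0.2))
wsdm <- function(x, y, factor = c("phi2", "phi")) {
  factor <- match.arg(factor)
  phi2 <- hoeffding_phi2(x, y)
  sw <- symbolic_weight(symbolize(x), symbolize(y))
  I <- if (factor == "phi2") phi2 else sqrt(phi2)
  structure(
    list(phi2 = phi2, sw = sw, wsdm = sw * I, n = length(x), factor = factor),
    class = "wsdm"
  )
}

#' @export
print.wsdm <- function(x, ...) {
  cat(sprintf(
    "wSDM dependence estimate (n = %d)\n  phi2 = %.4f  sw = %.4f  wsdm = %.4f%s\n",
    x$n, x$phi2, x$sw, x$wsdm,
    if (x$factor == "phi") "  (factor: sqrt(phi2))" else ""
  ))
  invisible(x)
}

#' Pairwise wSDM connectivity matrix
#'
#' Applies [wsdm()] to every pair of regions of a region x time matrix. The
#' diagonal is set to 1 by convention (the finite-sample self-dependence
#' estimate is 1 - O(1/n)); the matrix is exactly symmetric because both
#' factors of the metric are.
#'
#' @param series region x time numeric matrix with >= 2 rows (regions) and
#'   >= 8 columns (time points); row names are used as region labels.
#' @param factor Passed to [wsdm()].
#' @return A symmetric region x region numeric matrix.
#' @export
connectivity_matrix <- function(series, factor = c("phi2", "phi")) {
  factor <- match.arg(factor)
  if (!is.matrix(series) || nrow(series) < 2L)
    stop("'series' must be a region x time matrix with >= 2 regions")
  if (ncol(series) < 8L) stop("need at least 8 time points")
  p <- nrow(series)
  out <- diag(1, p)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      out[i, j] <- out[j, i] <- wsdm(series[i, ], series[j, ], factor)$wsdm
    }
  }
  dimnames(out) <- list(rownames(series), rownames(series))
  out
}
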