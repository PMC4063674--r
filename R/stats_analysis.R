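# Correlation analytics over classified instance groups: PCA with
# main-component selection, 3D orthogonal-distance-regression lines,
# two-sample Kolmogorov-Smirnov tests on per-axis level distributions, and
# the count aggregations behind the pairwise scatter maps.

# analysis-space column order (conductances as fraction of canonical,
# E_Leak in volts)
.analysis_cols <- c("SynS", "SynG", "P", "K2", "h", "CaS", "Leak", "E_Leak")

#' Build the analysis matrix of a group
#'
#' Converts instance records to analysis space: conductance levels as
#' fractions of canonical (0--1.75) and the leak reversal potential in
#' volts, in the fixed column order `SynS, SynG, P, K2, h, CaS, Leak,
#' E_Leak`. For burster (isolated) groups the two synaptic columns are
#' identically zero and are dropped, leaving six columns; other constant
#' columns are retained.
#'
#' @param group data.frame of instance records (e.g. from [query_group()])
#'   with percent-level columns and `E_Leak` in mV
#' @param drop_synaptic drop the all-zero synaptic columns; default: drop
#'   exactly when the whole group is isolated
#' @return Numeric matrix (rows = instances) with attribute `columns`.
#' @export
build_analysis_matrix <- function(group, drop_synaptic = NULL) {
  stopifnot(nrow(group) > 0)
  m <- cbind(SynS = group$SynS / 100, SynG = group$SynG / 100,
             P = group$P / 100, K2 = group$K2 / 100, h = group$h / 100,
             CaS = group$CaS / 100, Leak = group$Leak / 100,
             E_Leak = group$E_Leak / 1000)
  if (is.null(drop_synaptic))
    drop_synaptic <- all(group$SynS == 0 & group$SynG == 0)
  if (drop_synaptic) m <- m[, setdiff(colnames(m), c("SynS", "SynG")), drop = FALSE]
  if (anyNA(m)) stop("missing values in analysis matrix")
  structure(m, columns = colnames(m))
}

#' Principal component analysis of a parameter group
#'
#' Centered, unscaled PCA of the analysis matrix. Components are reported
#' with unit-norm coefficient vectors, variance fractions in percent
#' (nonincreasing, summing to 100), and `n_main`, the smallest number of
#' leading components whose cumulative variance exceeds the threshold
#' (95%). Component signs are fixed so each component's largest-magnitude
#' coefficient is negative.
#'
#' @param M numeric matrix from [build_analysis_matrix()] (or any
#'   instances-by-parameters matrix)
#' @param threshold cumulative-variance threshold (%) for the main
#'   components
#' @return An object of class `hco_pca`: `coefficients` (columns =
#'   components), `variance_pct`, `n_main`, `center`, `n`.
#' @export
pca_group <- function(M, threshold = 95) {
  stopifnot(is.matrix(M), nrow(M) >= 2)
  pr <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  W <- pr$rotation
  # sign convention: largest-|coefficient| entry of each component negative
  for (j in seq_len(ncol(W))) {
    k <- which.max(abs(W[, j]))
    if (W[k, j] > 0) W[, j] <- -W[, j]
  }
  v <- pr$sdev^2
  vpct <- 100 * v / sum(v)
  structure(list(coefficients = W, variance_pct = vpct,
                 n_main = select_main_components(vpct, threshold),
                 center = pr$center, n = nrow(M)),
            class = "hco_pca")
}

#' @export
print.hco_pca <- function(x, ...) {
  cat(sprintf("<hco_pca> n = %d, %d variables\n", x$n, nrow(x$coefficients)))
  cat("  variance (%):", paste(sprintf("%.2f", x$variance_pct), collapse = ", "), "\n")
  cat(sprintf("  main components (cumulative > 95%%): %d\n", x$n_main))
  invisible(x)
}

#' Smallest set of leading components exceeding a cumulative variance
#'
#' @param variances variance fractions (%) in nonincreasing order
#' @param threshold cumulative threshold (%), default 95
#' @return The minimal `k` with `sum(variances[1:k]) > threshold`.
#' @export
select_main_components <- function(variances, threshold = 95) {
  stopifnot(all(diff(variances) <= 1e-9))
  cs <- cumsum(variances)
  k <- which(cs > threshold)
  if (!length(k)) length(variances) else k[1]
}

#' 3D orthogonal-distance-regression line
#'
#' Fits the line through the centroid of a 3D point set that minimizes the
#' summed squared orthogonal distances (total least squares): its direction
#' is the leading principal component of the (optionally
#' multiplicity-weighted) point set. When `weights` are given, each point
#' contributes once per instance it represents.
#'
#' @param points numeric matrix with 3 columns
#' @param weights optional nonnegative instance multiplicities per row
#' @return An object of class `hco_odr`: `centroid`, `direction` (unit
#'   3-vector), `rss` (sum of squared orthogonal residuals).
#' @export
odr_line_3d <- function(points, weights = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 2)
  w <- if (is.null(weights)) rep(1, nrow(points)) else weights
  stopifnot(length(w) == nrow(points), all(w >= 0), sum(w) > 0)
  ctr <- colSums(points * w) / sum(w)
  X <- sweep(points, 2, ctr)
  S <- crossprod(X * sqrt(w)) # weighted scatter matrix
  if (sum(diag(S)) <= 0) stop("all points identical; line direction undefined")
  eg <- eigen(S, symmetric = TRUE)
  dir <- eg$vectors[, 1]
  k <- which.max(abs(dir))
  if (dir[k] > 0) dir <- -dir
  rss <- sum(diag(S)) - eg$values[1] # residual orthogonal scatter
  structure(list(centroid = ctr, direction = dir, rss = rss,
                 n = sum(w)), class = "hco_odr")
}

#' @export
print.hco_odr <- function(x, ...) {
  cat("<hco_odr line>\n")
  cat("  centroid:", paste(sprintf("%.4f", x$centroid), collapse = ", "), "\n")
  cat("  direction:", paste(sprintf("%.4f", x$direction), collapse = ", "), "\n")
  cat(sprintf("  orthogonal RSS: %.6g (weight %g)\n", x$rss, x$n))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided two-sample KS test: statistic
#' \eqn{k = \sup_x |F_1(x) - F_2(x)|} over the pooled sample points (exact
#' under ties), with the asymptotic p-value of the classical
#' Smirnov approximation using the small-sample-corrected argument
#' \eqn{\lambda = (\sqrt{n} + 0.12 + 0.11/\sqrt{n})\,k},
#' \eqn{n = n_1 n_2/(n_1+n_2)}. The null hypothesis (samples drawn from
#' the same distribution) is rejected at level `alpha`.
#'
#' @param x,y numeric samples (nonempty)
#' @param alpha significance level, default 0.05
#' @return An object of class `hco_ks`: `k`, `p`, `h` (reject flag),
#'   `n_eff`.
#' @export
ks_two_sample <- function(x, y, alpha = 0.05) {
  if (!length(x) || !length(y)) stop("empty sample")
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  pts <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(pts)
  Fy <- stats::ecdf(y)(pts)
  k <- max(abs(Fx - Fy))
  n <- length(x) * length(y) / (length(x) + length(y))
  lambda <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * k
  j <- 1:101
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * lambda^2 * j^2))
  p <- min(max(p, 0), 1)
  structure(list(k = k, p = p, h = p < alpha, n_eff = n, alpha = alpha),
            class = "hco_ks")
}

#' @export
print.hco_ks <- function(x, ...) {
  cat(sprintf("<hco_ks> k = %.4g, p = %.4g, reject at %.2g: %s\n",
              x$k, x$p, x$alpha, x$h))
  invisible(x)
}

#' Distribution of a group over one parameter's grid levels
#'
#' @param group data.frame of instance records
#' @param param one of the seven conductances (percent levels) or `E_Leak`
#' @param levels level set defining the bins (defaults to the standard
#'   grid levels for the parameter)
#' @return Named integer vector of counts per level (sums to the group
#'   size).
#' @export
axis_distribution <- function(group, param,
                              levels = if (param == "E_Leak")
                                c(-70, -65, -60, -55, -50)
                              else c(0, 25, 50, 75, 100, 125, 150, 175)) {
  stopifnot(param %in% c(.swept_conductances, "E_Leak"))
  v <- group[[param]]
  tab <- table(factor(v, levels = levels))
  stats::setNames(as.integer(tab), names(tab))
}

#' Pairwise count map of a group over two parameters
#'
#' Counts instances on the level lattice of two parameters. Display sizes
#' follow the screen's point-size rule `ln(count) + 1` (so a single
#' instance has size 1); empty cells get size 0.
#'
#' @param group data.frame of instance records
#' @param p1,p2 distinct parameter names
#' @param levels1,levels2 level sets (defaults as in [axis_distribution()])
#' @return List with `counts` (matrix, `p1` rows x `p2` columns) and
#'   `sizes`.
#' @export
pairwise_count_map <- function(group, p1, p2,
                               levels1 = NULL, levels2 = NULL) {
  if (p1 == p2) stop("p1 and p2 must differ")
  lv <- function(p, l) if (!is.null(l)) l else if (p == "E_Leak")
    c(-70, -65, -60, -55, -50) else c(0, 25, 50, 75, 100, 125, 150, 175)
  l1 <- lv(p1, levels1); l2 <- lv(p2, levels2)
  counts <- table(factor(group[[p1]], levels = l1),
                  factor(group[[p2]], levels = l2))
  counts <- matrix(as.integer(counts), nrow = length(l1),
                   dimnames = list(l1, l2))
  sizes <- ifelse(counts >= 1, log(counts) + 1, 0)
  list(counts = counts, sizes = sizes)
}
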