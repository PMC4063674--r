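make_group <- function(M) {
  # wrap an analysis-space matrix back into percent-level instance records
  df <- as.data.frame(M * 100)
  if ("E_Leak" %in% colnames(df)) df$E_Leak <- M[, "E_Leak"] * 1000
  df
}

test_that("analysis matrix uses the fixed column order and scaling", {
  grp <- data.frame(SynS = c(100, 100), SynG = c(100, 0), P = c(175, 0),
                    K2 = c(75, 100), h = c(100, 100), CaS = c(100, 100),
                    Leak = c(50, 125), E_Leak = c(-70, -50))
  M <- build_analysis_matrix(grp)
  expect_equal(colnames(M), c("SynS", "SynG", "P", "K2", "h", "CaS", "Leak", "E_Leak"))
  expect_equal(unname(M[1, "P"]), 1.75)
  expect_equal(unname(M[1, "E_Leak"]), -0.070)
  expect_equal(unname(M[2, "Leak"]), 1.25)
  # isolated group: synaptic columns dropped, six remain
  iso <- grp
  iso$SynS <- 0
  iso$SynG <- 0
  expect_equal(ncol(build_analysis_matrix(iso)), 6)
  expect_equal(ncol(M), 8)
})

test_that("PCA recovers exact low-rank structure and conserves variance", {
  set.seed(1)
  # points exactly on a 3D line: variance fractions {100, 0, 0}
  tpos <- rnorm(50)
  M <- cbind(1 + 2 * tpos, -1 + 0.5 * tpos, 3 * tpos)
  pc <- pca_group(M)
  expect_equal(pc$variance_pct, c(100, 0, 0), tolerance = 1e-9)
  expect_equal(pc$n_main, 1)
  # orthonormal coefficients, variance conservation vs total variance
  X <- matrix(rnorm(600), 100, 6)
  pc2 <- pca_group(X)
  expect_equal(crossprod(pc2$coefficients), diag(6), tolerance = 1e-9,
               ignore_attr = TRUE)
  tot <- sum(apply(X, 2, stats::var))
  expect_equal(sum(pc2$variance_pct), 100, tolerance = 1e-9)
  # independent oracle: eigenvalues of the covariance matrix
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(pc2$variance_pct, 100 * ev / sum(ev), tolerance = 1e-9)
  expect_equal(abs(det(crossprod(pc2$coefficients,
                                 eigen(stats::cov(X), symmetric = TRUE)$vectors))),
               1, tolerance = 1e-6)
})

test_that("isotropic clouds spread variance evenly across components", {
  set.seed(2)
  M <- matrix(rnorm(3e5), ncol = 3)
  pc <- pca_group(M)
  expect_true(all(abs(pc$variance_pct - 100 / 3) < 1))
})

test_that("main-component selection takes the smallest set above threshold", {
  expect_equal(select_main_components(c(60, 20, 10, 6, 3, 1)), 4)
  expect_equal(select_main_components(c(96, 4, 0)), 1)
  expect_equal(select_main_components(c(50, 30, 15, 5)), 4) # 95 is not > 95
  expect_equal(select_main_components(c(95, 5), threshold = 95), 2)
  expect_error(select_main_components(c(10, 60, 30)))
})

test_that("PCA direction recovery on synthetic correlated groups", {
  d <- c(1, -2, 0.5) / sqrt(sum(c(1, -2, 0.5)^2))
  M <- gen_correlated_group(500, d, spread = 1, sigma = 0.01, seed = 3)
  pc <- pca_group(M)
  v <- pc$coefficients[, 1]
  angle <- acos(min(1, abs(sum(v * d)))) * 180 / pi
  expect_lt(angle, 1)
  # noiseless points: first PC carries 100% of the variance
  M0 <- gen_correlated_group(200, d, spread = 1, sigma = 0, seed = 4)
  expect_equal(pca_group(M0)$variance_pct[1], 100, tolerance = 1e-9)
})

test_that("ODR line is the first-PC line and minimizes orthogonal residuals", {
  set.seed(5)
  tpos <- runif(40, -2, 2)
  pts <- cbind(tpos, 2 * tpos, -tpos) +
    matrix(rnorm(120, 0, 0.05), 40)
  fit <- odr_line_3d(pts)
  expect_equal(sqrt(sum(fit$direction^2)), 1, tolerance = 1e-12)
  expect_equal(fit$centroid, colMeans(pts), tolerance = 1e-12,
               ignore_attr = TRUE)
  # direction equals pca_group's first component (up to sign convention)
  pc1 <- pca_group(pts)$coefficients[, 1]
  expect_equal(abs(sum(fit$direction * pc1)), 1, tolerance = 1e-9)
  # collinear points: zero residual, direction along the line
  line <- cbind(1:10, 2 * (1:10), -3 * (1:10))
  fl <- odr_line_3d(line)
  expect_equal(fl$rss, 0, tolerance = 1e-9)
  expect_equal(abs(sum(fl$direction * c(1, 2, -3) / sqrt(14))), 1,
               tolerance = 1e-12)
  # oracle: the fitted direction beats 100 random directions through the
  # centroid
  rss_dir <- function(dirn) {
    X <- sweep(pts, 2, fit$centroid)
    sum(X^2) - sum((X %*% dirn)^2)
  }
  set.seed(6)
  for (i in 1:100) {
    rd <- rnorm(3)
    rd <- rd / sqrt(sum(rd^2))
    expect_lte(fit$rss, rss_dir(rd) + 1e-12)
  }
  # numeric minimization oracle over line angles
  obj <- function(ang) {
    dirn <- c(cos(ang[1]) * cos(ang[2]), cos(ang[1]) * sin(ang[2]), sin(ang[1]))
    rss_dir(dirn)
  }
  opt <- stats::optim(c(0.3, 0.3), obj)
  expect_lte(fit$rss, opt$value + 1e-8)
  expect_error(odr_line_3d(matrix(1, 5, 3)), "identical")
})

test_that("ODR multiplicity weighting equals row replication", {
  pts <- cbind(c(0, 1, 2, 3), c(0, 1.1, 1.9, 3.2), c(0, -1, -2, -3.1))
  w <- c(1, 3, 2, 1)
  fw <- odr_line_3d(pts, weights = w)
  frep <- odr_line_3d(pts[rep(1:4, w), ])
  expect_equal(fw$centroid, frep$centroid, tolerance = 1e-12)
  expect_equal(abs(sum(fw$direction * frep$direction)), 1, tolerance = 1e-12)
  expect_equal(fw$rss, frep$rss, tolerance = 1e-9)
})

test_that("KS statistic equals the brute-force ECDF oracle, ties included", {
  brute_k <- function(x, y) {
    pts <- c(x, y)
    max(vapply(pts, function(p) abs(mean(x <= p) - mean(y <= p)), numeric(1)))
  }
  set.seed(7)
  for (i in 1:20) {
    nx <- sample(2:200, 1)
    ny <- sample(2:200, 1)
    # heavily tied discrete samples, like grid-level data
    x <- sample(seq(0, 175, by = 25), nx, replace = TRUE)
    y <- sample(seq(0, 175, by = 25), ny, replace = TRUE)
    r <- ks_two_sample(x, y)
    expect_equal(r$k, brute_k(x, y), tolerance = 1e-12)
  }
  # continuous samples: agree with stats::ks.test's statistic
  x <- rnorm(80)
  y <- rnorm(120, 0.5)
  expect_equal(ks_two_sample(x, y)$k,
               unname(stats::ks.test(x, y)$statistic), tolerance = 1e-12)
  # asymptotic p-value close to R's for moderate n
  expect_equal(ks_two_sample(x, y)$p,
               stats::ks.test(x, y, exact = FALSE)$p.value, tolerance = 0.05)
})

test_that("KS degenerate cases and the rejection flag", {
  x <- c(1, 2, 3, 4, 5)
  r <- ks_two_sample(x, x)
  expect_equal(r$k, 0)
  expect_false(r$h)
  # fully separated supports
  r2 <- ks_two_sample(rep(1:3, 20), rep(10:12, 20))
  expect_equal(r2$k, 1)
  expect_true(r2$h)
  expect_true(r2$p < 0.05)
  expect_error(ks_two_sample(numeric(0), x), "empty")
})

test_that("axis distributions and pairwise count maps conserve group size", {
  set.seed(8)
  grp <- data.frame(P = sample(c(0, 25, 50, 75, 100, 125, 150, 175), 37, TRUE),
                    K2 = sample(c(0, 25, 50, 75, 100, 125, 150, 175), 37, TRUE),
                    Leak = 100, E_Leak = -60)
  h <- axis_distribution(grp, "P")
  expect_equal(sum(h), 37)
  expect_length(h, 8)
  # one-level group: single nonzero bin
  h2 <- axis_distribution(data.frame(K2 = rep(75, 5)), "K2")
  expect_equal(unname(h2[["75"]]), 5)
  expect_equal(sum(h2 > 0), 1)
  pm <- pairwise_count_map(grp, "P", "K2")
  expect_equal(sum(pm$counts), 37)
  # the point-size rule: ln(count) + 1
  expect_equal(pm$sizes[pm$counts == 1], rep(1, sum(pm$counts == 1)))
  expect_equal(unname(pairwise_count_map(
    data.frame(P = rep(0, round(exp(2))), K2 = rep(0, round(exp(2)))),
    "P", "K2")$sizes[1, 1]), log(round(exp(2))) + 1, tolerance = 0.1)
  expect_error(pairwise_count_map(grp, "P", "P"), "differ")
})
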