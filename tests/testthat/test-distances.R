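test_that("Bhattacharyya distance matches hand-computed angles", {
  p <- rbind(a = c(0.5, 0.5), b = c(0.5, 0.5), c = c(1, 0), d = c(0, 1),
             e = c(0.25, 0.75), f = c(0.75, 0.25))
  d <- dist_bhattacharyya(p)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["c", "d"], pi / 2)
  expect_equal(d["e", "f"], pi / 6, tolerance = 1e-12)
  expect_true(all(d >= 0 & d <= pi / 2 + 1e-12))
})

test_that("Bhattacharyya validation names the offending row", {
  bad_sum <- rbind(r1 = c(0.5, 0.5), r2 = c(0.6, 0.6))
  expect_error(dist_bhattacharyya(bad_sum), "r2")
  bad_neg <- rbind(r1 = c(0.5, 0.5), r2 = c(-0.1, 1.1))
  expect_error(dist_bhattacharyya(bad_neg), "r2")
})

test_that("Bhattacharyya distance is invariant to column permutation", {
  set.seed(11)
  for (i in 1:5) {
    x <- matrix(rexp(8 * 5), 8, 5)
    x <- x / rowSums(x)
    perm <- sample(5)
    expect_equal(dist_bhattacharyya(x), dist_bhattacharyya(x[, perm]),
                 tolerance = 1e-12)
  }
})

test_that("Gower distance reproduces hand-evaluated mixed-variable cases", {
  # two binary variables, full presence/absence mismatch: s = 0, d = sqrt(2)
  b <- data.frame(v1 = c(1, 0), v2 = c(1, 0))
  expect_equal(dist_gower(b, types = c("binary", "binary"))[1, 2], sqrt(2))
  # continuous (range 10, values 2 vs 7) + matching qualitative state:
  # s = ((1 - 0.5) + 1)/2 = 0.75, d = sqrt(0.5)
  m <- data.frame(cont = c(2, 7, 12), qual = c("x", "x", "y"))
  d <- dist_gower(m, types = c("continuous", "qualitative"))
  expect_equal(d[1, 2], sqrt(0.5))
  # identical complete rows
  same <- data.frame(a = c(1, 1), b = c("u", "u"))
  expect_equal(dist_gower(same)[1, 2], 0)
})

test_that("Gower drops terms involving missing values from both sides of the coefficient", {
  # pair comparable only on the qualitative variable (match): s = 1/1, d = 0
  x <- data.frame(cont = c(3, NA), qual = c("a", "a"))
  expect_equal(dist_gower(x, types = c("continuous", "qualitative"))[1, 2], 0)
  # absence-absence binary with a missing continuous: no comparable weight
  y <- data.frame(b = c(0, 0), cont = c(1, NA))
  expect_error(dist_gower(y, types = c("binary", "continuous")),
               "no comparable variable")
})

test_that("Gower on continuous data with equal ranges is a monotone transform of Manhattan", {
  set.seed(21)
  for (i in 1:5) {
    x <- matrix(runif(18), 6, 3)
    x <- apply(x, 2, function(v) (v - min(v)) / diff(range(v)))  # all ranges 1
    d <- dist_gower(as.data.frame(x))
    manh <- as.matrix(dist(x, method = "manhattan"))
    expect_equal(d, sqrt(2 * manh / 3), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("a constant continuous variable counts as a full match", {
  x <- data.frame(flat = c(5, 5, 5), v = c(0, 1, 2))
  d <- dist_gower(x)
  # s(1,2) = (1 + (1 - 0.5)) / 2 = 0.75
  expect_equal(d[1, 2], sqrt(2 * 0.25))
})

test_that("pairwise Mahalanobis equals Euclidean for whitened data and is affine invariant", {
  set.seed(31)
  x <- matrix(rnorm(60), 20, 3)
  xw <- x %*% solve(chol(cov(x)))   # sample covariance exactly identity
  expect_equal(dist_mahalanobis(xw), as.matrix(dist(xw)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diag(dist_mahalanobis(x)) == 0))
  for (i in 1:5) {
    y <- matrix(rnorm(24), 8, 3)
    A <- matrix(rnorm(9), 3, 3) + diag(3)
    shift <- rnorm(3)
    yt <- sweep(y %*% A, 2, shift, "+")
    expect_equal(dist_mahalanobis(y), dist_mahalanobis(yt), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("Mahalanobis pseudo-inverse ignores a duplicated column", {
  set.seed(32)
  x <- matrix(rnorm(15), 5, 3)
  xdup <- cbind(x, x[, 3])
  got <- dist_mahalanobis(xdup)
  # independent oracle: explicit pseudo-inverse quadratic form
  S <- cov(xdup)
  Sinv <- MASS::ginv(S)
  expected <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    v <- xdup[i, ] - xdup[j, ]
    expected[i, j] <- sqrt(max(drop(t(v) %*% Sinv %*% v), 0))
  }
  expect_equal(got, expected, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(got, dist_mahalanobis(x), tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(dist_mahalanobis(matrix(1, 4, 2)), "zero variance")
})

test_that("correlation distance matches hand-computed Pearson values", {
  x <- rbind(u = c(1, 2, 3), v = c(1, 2, 4), w = c(-1, -2, -3))
  d <- dist_correlation(x)
  r <- cor(c(1, 2, 3), c(1, 2, 4))
  expect_equal(d["u", "v"], sqrt(2 * (1 - r)))
  expect_equal(d["u", "v"], 0.18985, tolerance = 1e-4)
  expect_equal(d["u", "w"], 2)        # perfect anti-correlation
  expect_equal(d["u", "u"], 0)
  d1 <- dist_correlation(x, method = "one_minus_r")
  expect_equal(d1["u", "w"], 2)
  expect_equal(d1["u", "v"], 1 - r)
  expect_error(dist_correlation(rbind(c(1, 1, 1), c(1, 2, 3))), "constant profile")
})

test_that("all distance constructors yield valid distance matrices", {
  set.seed(41)
  freqs <- matrix(rexp(30), 6, 5); freqs <- freqs / rowSums(freqs)
  cont <- matrix(rnorm(30), 6, 5)
  mats <- list(dist_bhattacharyya(freqs),
               dist_gower(as.data.frame(cont)),
               dist_mahalanobis(cont),
               dist_correlation(cont))
  for (m in mats) {
    expect_true(isSymmetric(m, tol = 1e-8))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0))
  }
})
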