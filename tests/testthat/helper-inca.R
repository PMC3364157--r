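# Fixtures and independent oracles shared across the test files.
# Everything is generated in code under fixed seeds; no stored data.

# Gaussian clusters around given centres (one centre per row).
make_clusters <- function(centers, n_per, sd = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  centers <- as.matrix(centers)
  k <- nrow(centers)
  pts <- centers[rep(seq_len(k), each = n_per), , drop = FALSE] +
    matrix(rnorm(k * n_per * ncol(centers), 0, sd), k * n_per, ncol(centers))
  list(points = pts, labels = rep(seq_len(k), each = n_per))
}

euclid_to <- function(points, probe) {
  sqrt(colSums((t(points) - probe)^2))
}

# Independent oracle for the INCA statistic: direct numeric minimization of
# L(alpha) over the affine constraint, parameterized by k-1 free weights.
# Never touches the package's linear-system path.
brute_force_w <- function(phi2, delta2) {
  k <- length(phi2)
  if (k == 1) return(phi2)
  obj <- function(free) {
    a <- c(free, 1 - sum(free))
    sum(a * phi2) - 0.5 * drop(t(a) %*% delta2 %*% a)
  }
  grad <- function(free) {
    a <- c(free, 1 - sum(free))
    g <- phi2 - drop(delta2 %*% a)   # dL/d alpha
    g[seq_len(k - 1)] - g[k]         # chain rule through alpha_k = 1 - sum
  }
  starts <- rbind(rep(1 / k, k - 1),
                  diag(1, k - 1),
                  matrix(runif(3 * (k - 1), -1, 2), 3, k - 1))
  best <- Inf
  for (s in seq_len(nrow(starts))) {
    o <- optim(starts[s, ], obj, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15, abstol = 1e-14))
    if (o$value < best) best <- o$value
  }
  best
}

# Random rotation matrix (Haar via QR).
random_rotation <- function(d) {
  q <- qr.Q(qr(matrix(rnorm(d * d), d)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Per-repetition rejection rate of the typicality test over many typical
# probes: each probe is held out of its cluster (leave-one-out on the probe
# only) and tested against the remaining units.
type1_rejection_rate <- function(n_probes = 150, n_per = 20, np = 400,
                                 alpha = 0.05, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0))
  vapply(seq_len(n_probes), function(i) {
    cl <- make_clusters(centers, n_per, sd = 1)
    probe_idx <- sample(length(cl$labels), 1)
    ref <- setdiff(seq_along(cl$labels), probe_idx)
    d <- as.matrix(dist(cl$points))
    res <- inca_test(d[ref, ref], cl$labels[ref], d[ref, probe_idx],
                     np = np, alpha = alpha, P = 1,
                     seed = sample.int(2^30, 1))
    res$rejections / 10
  }, numeric(1))
}
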