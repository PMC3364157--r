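# Synthetic-data generators: module-structured expression tables,
# 6-timepoint time-course profiles in eight shape classes, and exact
# simplex configurations with a known analytic statistic.

#' Simulate module-structured expression data
#'
#' Emulates coexpression-module structure: each module has one latent
#' standard-normal profile ("eigengene") across samples, and each member
#' gene is \eqn{r \cdot \mathrm{profile} + \sqrt{1 - r^2} \cdot
#' \mathrm{noise}} with its own membership correlation r drawn uniformly
#' from `[cor_lo, cor_hi]` (positive correlations only, the signed-network
#' convention). Noise genes are pure standard normal, uncorrelated with
#' every latent profile in expectation.
#'
#' @param n_samples number of samples (rows of the expression table).
#' @param module_sizes integer vector of genes per module; ignored when
#'   `proportions` is given.
#' @param cor_lo,cor_hi bounds of the membership-correlation range,
#'   `0 < cor_lo <= cor_hi < 1`. Defaults 0.5 and 0.9 give well-separated
#'   modules with a realistic spread of hub-to-peripheral correlations.
#' @param n_noise number of unstructured noise genes appended after the
#'   module genes (label 0).
#' @param proportions optional: module proportions summing to at most 1,
#'   converted to sizes with [module_sizes_from_proportions()] applied to
#'   `n_genes`.
#' @param n_genes total gene count, required with `proportions`.
#' @param seed optional integer seed; a fixed seed makes the output
#'   bit-identical.
#' @return List of class `"sim_modules"`: `values` (samples x genes matrix,
#'   genes named `Gene.1`, ...), `labels` (module id per gene, 0 = noise)
#'   and `params`.
#' @examples
#' sim <- simulate_modules(20, c(15, 10), seed = 1)
#' table(sim$labels)
#' @export
simulate_modules <- function(n_samples = 100, module_sizes = c(480, 360, 360),
                             cor_lo = 0.5, cor_hi = 0.9, n_noise = 0,
                             proportions = NULL, n_genes = NULL, seed = NULL) {
  if (!is.null(proportions)) {
    if (is.null(n_genes)) stop("'n_genes' is required with 'proportions'", call. = FALSE)
    module_sizes <- module_sizes_from_proportions(n_genes, proportions)
    leftover <- n_genes - sum(module_sizes)
    if (leftover > 0 && n_noise == 0) n_noise <- leftover
  }
  if (any(module_sizes < 1)) stop("module sizes must be >= 1", call. = FALSE)
  if (!(cor_lo > 0 && cor_lo <= cor_hi && cor_hi < 1)) {
    stop("need 0 < cor_lo <= cor_hi < 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  k <- length(module_sizes)
  total <- sum(module_sizes) + n_noise
  eigengenes <- matrix(rnorm(n_samples * k), n_samples, k)
  values <- matrix(NA_real_, n_samples, total)
  labels <- c(rep(seq_len(k), module_sizes), integer(n_noise))
  rs <- numeric(total)
  g <- 0L
  for (j in seq_len(k)) {
    e <- as.numeric(scale(eigengenes[, j]))
    for (i in seq_len(module_sizes[j])) {
      g <- g + 1L
      r <- runif(1, cor_lo, cor_hi)
      rs[g] <- r
      values[, g] <- r * e + sqrt(1 - r^2) * rnorm(n_samples)
    }
  }
  if (n_noise > 0) {
    values[, (g + 1L):total] <- rnorm(n_samples * n_noise)
  }
  dimnames(values) <- list(paste0("Sample.", seq_len(n_samples)),
                           paste0("Gene.", seq_len(total)))
  names(labels) <- colnames(values)
  structure(list(values = values, labels = labels,
                 params = list(n_samples = n_samples, module_sizes = module_sizes,
                               cor_lo = cor_lo, cor_hi = cor_hi,
                               n_noise = n_noise, seed = seed,
                               membership_cor = rs)),
            class = "sim_modules")
}

#' Convert module proportions to exact sizes
#'
#' Rounds `n_genes * proportions` to integers, adjusting the largest module
#' so the sizes sum to `round(n_genes * sum(proportions))`; e.g. 1200 genes
#' at proportions 0.3/0.3/0.4 give modules of 360, 360 and 480 genes.
#'
#' @param n_genes total number of genes.
#' @param proportions numeric vector of per-module proportions (sum <= 1;
#'   any remainder is left for noise genes).
#' @return Integer vector of module sizes.
#' @export
module_sizes_from_proportions <- function(n_genes, proportions) {
  if (any(proportions <= 0) || sum(proportions) > 1 + 1e-8) {
    stop("'proportions' must be positive and sum to at most 1", call. = FALSE)
  }
  sizes <- round(n_genes * proportions)
  target <- round(n_genes * sum(proportions))
  sizes[which.max(sizes)] <- sizes[which.max(sizes)] + (target - sum(sizes))
  as.integer(sizes)
}

#' Class-mean templates of the eight time-course profiles
#'
#' Numeric realization of eight canonical 6-timepoint expression shapes:
#' G1 constant; G2 monotone increasing with a small difference between the
#' first and last timepoints (deliberately adjacent to G1); G3 constant over
#' timepoints 1-3, then monotone increasing; G4 up-down with maximum at
#' timepoint 2; G5 up-down with maximum at 5; G6 down-up with minimum at 3;
#' G7 cyclic with maximum at 2 and minimum at 5; G8 down-up with minimum at
#' 2 and constant over timepoints 3-6.
#'
#' @return An 8 x 6 matrix of class means (rows `G1`...`G8`).
#' @export
time_course_templates <- function() {
  rbind(
    G1 = c(1.0, 1.00, 1.00, 1.00, 1.00, 1.00),
    G2 = c(1.0, 1.08, 1.16, 1.24, 1.32, 1.40),
    G3 = c(1.0, 1.00, 1.00, 1.60, 2.20, 2.80),
    G4 = c(1.0, 2.50, 1.80, 1.30, 0.90, 0.60),
    G5 = c(0.6, 0.90, 1.40, 2.00, 2.60, 1.40),
    G6 = c(2.2, 1.40, 0.60, 1.20, 1.90, 2.60),
    G7 = c(1.5, 2.50, 1.60, 0.90, 0.40, 1.30),
    G8 = c(2.2, 0.80, 1.60, 1.60, 1.60, 1.60)
  )
}

#' Simulate time-course expression profiles in eight shape classes
#'
#' Each gene follows its class-mean template (see
#' [time_course_templates()]) plus i.i.d. Gaussian noise on every
#' timepoint. With the defaults (15 genes per class, `noise_sd = 0.1`) the
#' classes are well separated except G1/G2, whose shapes are deliberately
#' close.
#'
#' @param genes_per_group genes per shape class (default 15, i.e. a
#'   120 x 6 table).
#' @param noise_sd standard deviation of the per-timepoint noise; 0 gives
#'   every gene exactly its template.
#' @param seed optional integer seed.
#' @return List of class `"sim_time_course"`: `values` (genes x 6 matrix),
#'   `labels` (class 1..8 per gene), `noise_sd` and `templates`.
#' @examples
#' tc <- simulate_time_course(seed = 1)
#' dim(tc$values)   # 120 x 6
#' @export
simulate_time_course <- function(genes_per_group = 15, noise_sd = 0.1, seed = NULL) {
  if (genes_per_group < 1) stop("'genes_per_group' must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  templates <- time_course_templates()
  n <- 8L * genes_per_group
  values <- templates[rep(seq_len(8), each = genes_per_group), , drop = FALSE] +
    matrix(rnorm(n * 6L, 0, noise_sd), n, 6L)
  labels <- rep(seq_len(8), each = genes_per_group)
  dimnames(values) <- list(paste0("Gene.", seq_len(n)), paste0("T", 1:6))
  names(labels) <- rownames(values)
  structure(list(values = values, labels = labels, noise_sd = noise_sd,
                 templates = templates, seed = seed),
            class = "sim_time_course")
}

#' Exact simplex configuration with a known INCA statistic
#'
#' Builds k clusters of points around the vertices of a regular simplex in
#' `dim`-dimensional space and places a probe at orthogonal height
#' `probe_offset` above the centroid of the vertices. For `spread = 0` the
#' squared height is known exactly: \eqn{W = \mathrm{probe\_offset}^2}.
#' Useful as an oracle for the height interpretation of the statistic and
#' for its k >= p degeneracy (with `k = dim + 1` the vertices affinely span
#' the space, no orthogonal direction remains, and only `probe_offset = 0`
#' is admissible, giving W = 0).
#'
#' @param k number of clusters (simplex vertices), `k <= dim + 1`.
#' @param dim embedding dimension.
#' @param spread standard deviation of isotropic Gaussian jitter around
#'   each vertex (0 = points exactly at the vertices).
#' @param probe_offset orthogonal height of the probe above the vertex
#'   hyperplane.
#' @param n_per points per cluster.
#' @param seed optional integer seed (only the jitter is random).
#' @return List with `d` (distance matrix of the cluster points), `pert`
#'   (labels), `d_probe` (distances probe -> points), `W_analytic`
#'   (`probe_offset^2`), `points` and `probe`.
#' @examples
#' fx <- simplex_fixture(k = 3, dim = 3, probe_offset = 2)
#' inca_w(fx$d, fx$d_probe, fx$pert)$W   # 4
#' @export
simplex_fixture <- function(k, dim, spread = 0, probe_offset = 1, n_per = 3,
                            seed = NULL) {
  if (k < 1) stop("'k' must be >= 1", call. = FALSE)
  if (k > dim + 1) stop(sprintf("'k' = %d exceeds dim + 1 = %d", k, dim + 1), call. = FALSE)
  if (k == dim + 1 && probe_offset != 0) {
    stop("with k = dim + 1 the vertices affinely span the space: only probe_offset = 0 is possible",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  # vertices: scaled standard basis vectors of R^k, embedded in R^dim when
  # k <= dim; for k = dim + 1 the basis simplex of R^k is rotated down into
  # its (k-1)-dimensional affine hull
  if (k <= dim) {
    vertices <- matrix(0, k, dim)
    vertices[cbind(seq_len(k), seq_len(k))] <- 1
    # unit normal to the vertex hyperplane inside span(e_1..e_k)
    u <- c(rep(1 / sqrt(k), k), rep(0, dim - k))
  } else {
    basis <- diag(k)
    centred <- sweep(basis, 2, colMeans(basis))
    e <- eigen(tcrossprod(centred), symmetric = TRUE)
    coords <- e$vectors[, seq_len(k - 1), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(k - 1)], 0)), nrow = k - 1)
    vertices <- cbind(coords, matrix(0, k, dim - (k - 1)))
    u <- rep(0, dim)  # unused: probe_offset is 0 here
  }
  centroid <- colMeans(vertices)
  probe <- centroid + probe_offset * u
  points <- vertices[rep(seq_len(k), each = n_per), , drop = FALSE]
  if (spread > 0) points <- points + matrix(rnorm(length(points), 0, spread),
                                            nrow(points), dim)
  pert <- rep(seq_len(k), each = n_per)
  d <- as.matrix(dist(points))
  d_probe <- sqrt(colSums((t(points) - probe)^2))
  list(d = d, pert = pert, d_probe = d_probe,
       W_analytic = probe_offset^2, points = points, probe = probe)
}
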