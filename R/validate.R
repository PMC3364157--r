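# Shared validation of the two objects every statistic consumes: a square
# symmetric distance matrix and a partition label vector.

# Coerce a dist object / square matrix to a validated numeric matrix.
# Symmetry is enforced within `sym_tol`: asymmetries below it are averaged
# away (with a warning when non-trivial), above it are an error.
as_distance_matrix <- function(d, arg = "d", sym_tol = 1e-8) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (is.data.frame(d)) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d)) {
    stop(sprintf("'%s' must be a numeric distance matrix or a 'dist' object", arg), call. = FALSE)
  }
  if (nrow(d) != ncol(d)) {
    stop(sprintf("'%s' must be square: got %d x %d", arg, nrow(d), ncol(d)), call. = FALSE)
  }
  if (anyNA(d) || any(!is.finite(d))) {
    bad <- which(!is.finite(d), arr.ind = TRUE)[1L, ]
    stop(sprintf("'%s' has a non-finite entry at row %d, column %d", arg, bad[1L], bad[2L]),
         call. = FALSE)
  }
  asym <- max(abs(d - t(d)))
  if (asym > sym_tol) {
    stop(sprintf("'%s' is not symmetric (max |d - t(d)| = %.3g)", arg, asym), call. = FALSE)
  }
  if (asym > 0) {
    if (asym > 1e-12) {
      warning(sprintf("'%s' symmetrized (max asymmetry %.3g)", arg, asym), call. = FALSE)
    }
    d <- (d + t(d)) / 2
  }
  if (any(d < 0)) {
    bad <- which(d < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("'%s' has a negative entry at row %d, column %d", arg, bad[1L], bad[2L]),
         call. = FALSE)
  }
  if (any(diag(d) != 0)) {
    if (max(diag(d)) > sym_tol) {
      stop(sprintf("'%s' has a non-zero diagonal (max %.3g)", arg, max(diag(d))), call. = FALSE)
    }
    diag(d) <- 0
  }
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- as.character(seq_len(nrow(d)))
  }
  d
}

# Normalise a partition label vector (integer, factor or character) to
# consecutive integer labels 1..k, keeping the original labels as names of
# the group vector. Non-consecutive positive integers are remapped with a
# warning, mirroring the convention that labels are "1, 2, 3, ...".
as_partition <- function(pert, n, arg = "pert") {
  if (length(pert) != n) {
    stop(sprintf("'%s' has length %d but the distance matrix has %d units",
                 arg, length(pert), n), call. = FALSE)
  }
  if (anyNA(pert)) stop(sprintf("'%s' contains missing labels", arg), call. = FALSE)
  if (is.factor(pert) || is.character(pert)) {
    f <- factor(pert)
  } else {
    if (!is.numeric(pert) || any(pert != floor(pert)) || any(pert < 1)) {
      stop(sprintf("'%s' labels must be positive integers (or a factor)", arg), call. = FALSE)
    }
    f <- factor(pert, levels = sort(unique(pert)))
    if (!identical(sort(unique(as.integer(pert))), seq_len(nlevels(f)))) {
      warning(sprintf("'%s' labels are not consecutive integers; remapped to 1..%d",
                      arg, nlevels(f)), call. = FALSE)
    }
  }
  labels <- as.integer(f)
  sizes <- tabulate(labels, nbins = nlevels(f))
  list(labels = labels, k = nlevels(f), sizes = sizes, groups = levels(f))
}

# Distances from one probe unit to the n reference units.
as_probe_distances <- function(dx0, n, arg = "d_test") {
  dx0 <- as.numeric(dx0)
  if (length(dx0) != n) {
    stop(sprintf("'%s' has length %d but there are %d reference units",
                 arg, length(dx0), n), call. = FALSE)
  }
  if (anyNA(dx0) || any(!is.finite(dx0))) {
    stop(sprintf("'%s' contains non-finite distances", arg), call. = FALSE)
  }
  if (any(dx0 < 0)) stop(sprintf("'%s' contains negative distances", arg), call. = FALSE)
  dx0
}
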