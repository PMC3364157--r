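#' INCA index across candidate numbers of clusters
#'
#' Computes the INCA index for partitions into k = 2, ..., K clusters and,
#' optionally, repeats the scan after removing "noise" units. Partitions
#' come from Partitioning Around Medoids ([cluster::pam()]) or
#' agglomerative clustering ([cluster::agnes()]: UPGMA `"average"`,
#' `"single"`, `"complete"`, `"ward"`, WPGMA `"weighted"`), or are supplied
#' by the user with `method = "partition"`.
#'
#' Noise screening: with an integer `L >= 1`, any unit that falls into a
#' cluster of size `<= L` in any of the k = 2..K partitions is flagged as a
#' noise unit. With `L = "custom"` the flags are taken from the `noise`
#' argument. The flagged units are removed, the remaining units are
#' re-clustered for each k, and a second index curve is reported: a handful
#' of stray units can hide an otherwise clear cluster structure, and the
#' denoised curve reveals it.
#'
#' @inheritParams geometric_variability
#' @param K largest number of clusters to consider (2 <= K < n). Ignored
#'   when `method = "partition"`.
#' @param method clustering back-end: `"pam"` (default), `"average"`,
#'   `"single"`, `"complete"`, `"ward"`, `"weighted"`, or `"partition"`.
#' @param pert for `method = "partition"`: a matrix (or data frame) with one
#'   column per candidate partition, each column giving group labels for all
#'   units.
#' @param noise for `L = "custom"`: logical vector flagging the noise units
#'   (or a vector of unit ids/indices).
#' @param L `NULL` for no noise handling, a positive integer for the
#'   small-cluster rule, or `"custom"` to use `noise`.
#' @return An object of class `"inca_curve"`: list with `ks`, `index_all`,
#'   `index_denoised` (`NULL` when no noise handling was requested),
#'   `noise` (named logical vector), `method` and `n`.
#' @examples
#' set.seed(1)
#' pts <- rbind(matrix(rnorm(30, 0), 15), matrix(rnorm(30, 6), 15))
#' curve <- inca_curve(dist(pts), K = 5, method = "average")
#' estimate_k(curve)
#' @export
inca_curve <- function(d, K = 10,
                       method = c("pam", "average", "single", "complete",
                                  "ward", "weighted", "partition"),
                       pert = NULL, noise = NULL, L = NULL) {
  method <- match.arg(method)
  dm <- as_distance_matrix(d)
  n <- nrow(dm)
  ids <- rownames(dm)

  if (method == "partition") {
    if (is.null(pert)) stop("method = \"partition\" requires 'pert'", call. = FALSE)
    pmat <- as.matrix(pert)
    if (nrow(pmat) != n) {
      stop(sprintf("'pert' has %d rows but the distance matrix has %d units",
                   nrow(pmat), n), call. = FALSE)
    }
    parts <- lapply(seq_len(ncol(pmat)), function(j) as_partition(pmat[, j], n)$labels)
    ks <- vapply(parts, max, integer(1))
  } else {
    if (!is.numeric(K) || length(K) != 1 || K < 2 || K >= n) {
      stop(sprintf("'K' must satisfy 2 <= K < n = %d", n), call. = FALSE)
    }
    K <- as.integer(K)
    ks <- 2:K
    parts <- cut_partitions(dm, ks, method)
  }
  index_all <- vapply(seq_along(parts), function(i) {
    if (max(parts[[i]]) < 2) return(NA_real_)
    inca_index(dm, parts[[i]])$total
  }, numeric(1))

  noise_flags <- NULL
  index_denoised <- NULL
  if (!is.null(L)) {
    if (identical(L, "custom")) {
      noise_flags <- normalize_noise(noise, n, ids)
    } else {
      if (!is.numeric(L) || length(L) != 1 || L < 1) {
        stop("'L' must be NULL, a positive integer, or \"custom\"", call. = FALSE)
      }
      if (L >= n) stop(sprintf("'L' must be smaller than n = %d", n), call. = FALSE)
      noise_flags <- Reduce(`|`, lapply(parts, function(lab) {
        sizes <- tabulate(lab)
        sizes[lab] <= L
      }))
    }
    names(noise_flags) <- ids
    keep <- !noise_flags
    if (sum(keep) > 2) {
      dsub <- dm[keep, keep, drop = FALSE]
      if (method == "partition") {
        subparts <- lapply(parts, function(lab) {
          sl <- lab[keep]
          match(sl, sort(unique(sl)))
        })
      } else {
        ks_sub <- ks[ks < sum(keep)]
        subparts <- cut_partitions(dsub, ks_sub, method)
        if (length(ks_sub) < length(ks)) {
          subparts <- c(subparts, vector("list", length(ks) - length(ks_sub)))
        }
      }
      index_denoised <- vapply(seq_along(parts), function(i) {
        lab <- subparts[[i]]
        if (is.null(lab) || max(lab) < 2) return(NA_real_)
        inca_index(dsub, lab)$total
      }, numeric(1))
    } else {
      index_denoised <- rep(NA_real_, length(parts))
    }
  }

  structure(list(ks = ks, index_all = index_all, index_denoised = index_denoised,
                 noise = noise_flags, method = method, n = n,
                 backend = paste0("cluster ", packageVersion("cluster"))),
            class = "inca_curve")
}

# Partitions at each k from the chosen back-end.
cut_partitions <- function(dm, ks, method) {
  dd <- as.dist(dm)
  if (method == "pam") {
    lapply(ks, function(k) cluster::pam(dd, k, diss = TRUE, cluster.only = TRUE))
  } else {
    hc <- as.hclust(cluster::agnes(dd, diss = TRUE, method = method))
    lapply(ks, function(k) unname(cutree(hc, k = k)))
  }
}

normalize_noise <- function(noise, n, ids) {
  if (is.null(noise)) return(rep(FALSE, n))  # empty custom list: nothing flagged
  if (is.logical(noise)) {
    if (length(noise) != n) {
      stop(sprintf("'noise' has length %d but there are %d units", length(noise), n),
           call. = FALSE)
    }
    return(noise)
  }
  flags <- rep(FALSE, n)
  if (is.character(noise)) {
    miss <- setdiff(noise, ids)
    if (length(miss)) stop(sprintf("unknown noise unit id '%s'", miss[1L]), call. = FALSE)
    flags[match(noise, ids)] <- TRUE
  } else {
    if (any(noise < 1 | noise > n)) stop("noise unit index out of range", call. = FALSE)
    flags[as.integer(noise)] <- TRUE
  }
  flags
}

#' Decide the number of clusters from an INCA curve
#'
#' The curve INCA_k over k = 2..K is read with two rules. If the whole
#' curve stays below `structure_threshold`, the data carry no cluster
#' structure (a low flat curve). Otherwise the estimate is the k after
#' which the index shows its decisive fall: among the k whose index is at
#' least `structure_threshold` and that were reached by a rise
#' (\eqn{INCA_k \ge INCA_{k-1}}), the one with the largest drop
#' \eqn{INCA_k - INCA_{k+1} > 0} wins (first on ties). If no drop sits on a
#' rise -- a monotonically falling curve -- every positive drop from a value
#' above the threshold competes. The rise condition keeps incidental
#' descents in the tail of a bumpy curve from masking the true fall.
#'
#' @param curve an `"inca_curve"` object, or a numeric vector of index
#'   values (taken to correspond to k = 2, 3, ...).
#' @param structure_threshold curves entirely below this value are declared
#'   structureless; default 0.2.
#' @param which use the `"all"`-units curve or the `"denoised"` one.
#' @return An object of class `"inca_k_estimate"`: list with `k` (integer,
#'   `NA` when no structure), `no_structure` (logical), `drops` and `ks`.
#' @examples
#' estimate_k(c(0.9, 0.85, 0.3, 0.25))     # k = 3
#' estimate_k(c(0.05, 0.06, 0.04, 0.05))   # no structure
#' @export
estimate_k <- function(curve, structure_threshold = 0.2,
                       which = c("all", "denoised")) {
  which <- match.arg(which)
  if (inherits(curve, "inca_curve")) {
    v <- if (which == "denoised") curve$index_denoised else curve$index_all
    if (is.null(v)) stop("the curve has no denoised index", call. = FALSE)
    ks <- curve$ks
  } else {
    v <- as.numeric(curve)
    ks <- seq(2, length.out = length(v))
  }
  ok <- !is.na(v)
  v <- v[ok]; ks <- ks[ok]
  if (length(v) < 2) stop("need index values for at least two values of k", call. = FALSE)

  if (max(v) < structure_threshold) {
    out <- list(k = NA_integer_, no_structure = TRUE, drops = NULL, ks = ks)
    return(structure(out, class = "inca_k_estimate"))
  }
  m <- length(v)
  drops <- v[-m] - v[-1]                       # drop after k = ks[i]
  names(drops) <- ks[-m]
  high <- v[-m] >= structure_threshold
  rose <- c(FALSE, v[-1][-(m - 1)] >= v[-m][-(m - 1)])  # v[i] >= v[i-1], i >= 2
  eligible <- which(high & rose & drops > 0)
  if (!length(eligible)) eligible <- which(high & drops > 0)
  if (!length(eligible)) {
    # curve never falls from a high value: take the k with the largest index
    k_hat <- ks[which.max(v)]
  } else {
    k_hat <- ks[eligible[which.max(drops[eligible])]]
  }
  structure(list(k = as.integer(k_hat), no_structure = FALSE,
                 drops = drops, ks = ks),
            class = "inca_k_estimate")
}

#' @export
print.inca_k_estimate <- function(x, ...) {
  if (x$no_structure) {
    cat("No cluster structure: the INCA index stays low for every k\n")
  } else {
    cat("Estimated number of clusters: k =", x$k, "\n")
  }
  invisible(x)
}

#' @export
print.inca_curve <- function(x, ...) {
  cat("INCA index to estimate the number of clusters considering all units\n")
  cat("Clustering method:", x$method, "\n")
  for (i in seq_along(x$ks)) {
    cat(sprintf("k = %d, %.4g\n", x$ks[i], x$index_all[i]))
  }
  if (!is.null(x$noise)) {
    cat("\nNoise units:\n")
    nz <- names(x$noise)[x$noise]
    if (length(nz)) cat(strwrap(paste(nz, collapse = " ")), sep = "\n") else cat("(none)\n")
    cat("\nINCA index without the noise units\n")
    for (i in seq_along(x$ks)) {
      cat(sprintf("k = %d, %.4g\n", x$ks[i], x$index_denoised[i]))
    }
  }
  invisible(x)
}

#' @describeIn inca_curve plot the index against k (both curves when noise
#'   units were screened).
#' @param x an `"inca_curve"` object.
#' @param ... further arguments passed to [base::plot()].
#' @export
plot.inca_curve <- function(x, ...) {
  has_denoised <- !is.null(x$index_denoised)
  ylim <- range(0, x$index_all, if (has_denoised) x$index_denoised, na.rm = TRUE)
  plot(x$ks, x$index_all, type = "b", pch = 19, ylim = ylim,
       xlab = "number of clusters k", ylab = "INCA index", ...)
  if (has_denoised) {
    lines(x$ks, x$index_denoised, type = "b", pch = 1, lty = 2)
    legend("topright", legend = c("all units", "without noise units"),
           pch = c(19, 1), lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
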