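#' Geometric variability of each group
#'
#' The geometric variability of a group \eqn{C_j} with \eqn{n_j} members is
#' \deqn{\hat V_\delta(C_j) = \frac{1}{2 n_j^2} \sum_{l,m} \delta^2(g_l, g_m),}
#' half the mean squared pairwise distance within the group, taken over all
#' ordered pairs (the \eqn{l = m} terms contribute zero). It is the
#' distance-based analogue of a within-group variance: for Euclidean
#' \eqn{\delta} it equals the mean squared distance of the members to their
#' centroid.
#'
#' @param d distance matrix (square numeric matrix or `dist` object).
#' @param pert partition labels for the units, positive integers or a factor.
#'   The default is a single group.
#' @return Named numeric vector with one non-negative variability per group.
#' @examples
#' pts <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))  # equilateral, side 1
#' geometric_variability(dist(pts), rep(1, 3))           # 1/3
#' @seealso [between_group_distances()], [proximity()]
#' @export
geometric_variability <- function(d, pert = rep(1L, nrow(as.matrix(d)))) {
  dm <- as_distance_matrix(d)
  part <- as_partition(pert, nrow(dm))
  D2 <- dm^2
  v <- vapply(seq_len(part$k), function(j) {
    idx <- part$labels == j
    sum(D2[idx, idx]) / (2 * part$sizes[j]^2)
  }, numeric(1))
  names(v) <- part$groups
  v
}

#' Squared distances between all pairs of groups
#'
#' For groups \eqn{C_i} and \eqn{C_j} the squared between-group distance is
#' \deqn{\hat\Delta^2_{ij} = \frac{1}{n_i n_j} \sum_{l,m}
#'   \delta^2(g^i_l, g^j_m) - \hat V_\delta(C_i) - \hat V_\delta(C_j),}
#' the mean squared cross-group distance with both within-group
#' variabilities removed. For a Euclidean \eqn{\delta} this is exactly the
#' squared distance between the group centroids; for non-Euclidean
#' dissimilarities small negative values can occur and are kept (with a
#' warning) rather than truncated.
#'
#' @inheritParams geometric_variability
#' @return An object of class `"group_geometry"`: a list with components
#'   `variabilities` (per-group \eqn{\hat V}), `delta2` (symmetric k x k
#'   matrix of \eqn{\hat\Delta^2} with zero diagonal), `sizes` and `groups`.
#' @examples
#' pts <- rbind(c(0, 0), c(3, 0))
#' between_group_distances(dist(pts), c(1, 2))$delta2   # 9
#' @export
between_group_distances <- function(d, pert = rep(1L, nrow(as.matrix(d)))) {
  dm <- as_distance_matrix(d)
  part <- as_partition(pert, nrow(dm))
  D2 <- dm^2
  v <- vapply(seq_len(part$k), function(j) {
    idx <- part$labels == j
    sum(D2[idx, idx]) / (2 * part$sizes[j]^2)
  }, numeric(1))
  k <- part$k
  delta2 <- matrix(0, k, k, dimnames = list(part$groups, part$groups))
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        a <- part$labels == i
        b <- part$labels == j
        delta2[i, j] <- delta2[j, i] <- mean(D2[a, b]) - v[i] - v[j]
      }
    }
    if (min(delta2) < -1e-8 * max(abs(delta2), 1)) {
      warning("negative squared between-group distances: the dissimilarity is not Euclidean-embeddable",
              call. = FALSE)
    }
  }
  structure(list(variabilities = setNames(v, part$groups), delta2 = delta2,
                 sizes = part$sizes, groups = part$groups),
            class = "group_geometry")
}

#' Proximity of a unit to each group
#'
#' The proximity function of a unit \eqn{g_0} to group \eqn{C_j} is
#' \deqn{\hat\phi^2(g_0, C_j) = \frac{1}{n_j} \sum_l \delta^2(g_0, g^j_l)
#'   - \hat V_\delta(C_j),}
#' the mean squared distance from \eqn{g_0} to the members of \eqn{C_j}
#' minus the group's geometric variability: the squared distance from
#' \eqn{g_0} to the group's centre, expressed purely through distances.
#'
#' @param dx0 numeric vector of distances from the unit \eqn{g_0} to the
#'   n reference units, in the same order as the partition labels.
#' @param pert partition labels of the n reference units.
#' @param variabilities per-group geometric variabilities as returned by
#'   [geometric_variability()] (or a `"group_geometry"` object).
#' @return Numeric vector of k proximities \eqn{\hat\phi^2(g_0, C_j)}.
#' @examples
#' pts <- rbind(c(0, 0), c(1, 0))
#' v <- geometric_variability(dist(pts), c(1, 1))
#' proximity(c(1, 1), c(1, 1), v)   # 1 - 1/4 = 3/4
#' @export
proximity <- function(dx0, pert, variabilities) {
  if (inherits(variabilities, "group_geometry")) variabilities <- variabilities$variabilities
  n <- length(dx0)
  dx0 <- as_probe_distances(dx0, n, arg = "dx0")
  part <- as_partition(pert, n)
  if (length(variabilities) != part$k) {
    stop(sprintf("'variabilities' has length %d but the partition has %d groups",
                 length(variabilities), part$k), call. = FALSE)
  }
  phi2 <- vapply(seq_len(part$k), function(j) {
    mean(dx0[part$labels == j]^2) - variabilities[[j]]
  }, numeric(1))
  setNames(phi2, part$groups)
}

#' The INCA statistic of a unit with respect to a partition
#'
#' The statistic is the constrained minimum
#' \deqn{W(g_0) = \min_{\alpha,\ \sum_i \alpha_i = 1} \Big\{ \sum_i \alpha_i
#'   \hat\phi^2_i(g_0) - \sum_{i<j} \alpha_i \alpha_j \hat\Delta^2_{ij} \Big\},}
#' which trades the weighted proximity of \eqn{g_0} to the clusters against
#' the weighted between-cluster separation. Geometrically \eqn{W(g_0)} is
#' the squared orthogonal height of \eqn{g_0} above the hyperplane through
#' the cluster centres; units far from that hyperplane are candidates for a
#' novel group. The minimum is found from the stationary conditions of the
#' Lagrangian, the linear system
#' \eqn{[\hat\Delta^2 \alpha + \lambda 1 = \hat\phi^2,\ 1^\top\alpha = 1]},
#' with a pseudo-inverse fallback when the system is singular. When the
#' cluster centres affinely span the whole embedding space (number of
#' clusters \eqn{k \ge} embedding dimension \eqn{p}) the height is
#' identically zero and the result is flagged `degenerate`.
#'
#' The weights \eqn{\alpha_i} are not sign-constrained: the hyperplane
#' through the centres is their affine hull. Tiny negative \eqn{W} from
#' floating-point noise is clamped to zero; larger negative values, which
#' can arise for non-Euclidean dissimilarities, are kept and flagged.
#'
#' @param phi2 proximities of the unit to the k groups, from [proximity()].
#' @param geometry a `"group_geometry"` object from
#'   [between_group_distances()], or the k x k matrix \eqn{\hat\Delta^2}.
#' @return An object of class `"inca_stat"`: list with `W` (the statistic),
#'   `alpha` (weights summing to 1), `U` (projections
#'   \eqn{U_j = \hat\phi^2_j - W}), and logical flags `degenerate` and
#'   `negative`.
#' @examples
#' # two singleton clusters at (0,0) and (2,0); probe at (1,1)
#' phi2 <- c(2, 2); delta2 <- matrix(c(0, 4, 4, 0), 2)
#' inca_statistic(phi2, delta2)   # W = 1 (squared height of the triangle)
#' @seealso [inca_w()] to compute it straight from distances, [allocate()]
#' @export
inca_statistic <- function(phi2, geometry) {
  delta2 <- if (inherits(geometry, "group_geometry")) geometry$delta2 else geometry
  phi2 <- as.numeric(phi2)
  k <- length(phi2)
  if (k == 0) stop("'phi2' is empty", call. = FALSE)
  if (k == 1) {
    return(structure(list(W = phi2, alpha = 1, U = 0,
                          degenerate = FALSE, negative = phi2 < 0),
                     class = "inca_stat"))
  }
  if (!is.matrix(delta2) || nrow(delta2) != k || ncol(delta2) != k) {
    stop(sprintf("'geometry' must carry a %d x %d squared-distance matrix", k, k),
         call. = FALSE)
  }
  M <- rbind(cbind(delta2, 1), c(rep(1, k), 0))
  b <- c(phi2, 1)
  degenerate <- FALSE
  x <- tryCatch(solve(M, b), error = function(e) NULL)
  if (is.null(x)) {
    x <- drop(MASS::ginv(M) %*% b)
    # consistency check: an unresolvable system means the centres' hyperplane
    # fills the space and the height is zero
    if (max(abs(M %*% x - b)) > 1e-6 * max(1, max(abs(b)))) {
      degenerate <- TRUE
    }
  }
  alpha <- x[seq_len(k)]
  W <- sum(alpha * phi2) - 0.5 * drop(crossprod(alpha, delta2 %*% alpha))
  if (degenerate) W <- 0
  negative <- FALSE
  if (W < 0) {
    if (W > -1e-8 * max(abs(phi2), 1)) {
      W <- 0
    } else {
      negative <- TRUE
    }
  }
  structure(list(W = W, alpha = setNames(alpha, names(phi2)),
                 U = setNames(phi2 - W, names(phi2)),
                 degenerate = degenerate, negative = negative),
            class = "inca_stat")
}

#' INCA statistic straight from a distance matrix
#'
#' Convenience wrapper chaining [geometric_variability()],
#' [between_group_distances()], [proximity()] and [inca_statistic()] for a
#' single unit described by its distances to the reference units.
#'
#' @inheritParams geometric_variability
#' @param dx0 distances from the unit to the n reference units.
#' @return An `"inca_stat"` object, see [inca_statistic()].
#' @examples
#' pts <- rbind(c(0, 0), c(2, 0))
#' inca_w(dist(pts), c(sqrt(2), sqrt(2)), c(1, 2))$W   # 1
#' @export
inca_w <- function(d, dx0, pert) {
  dm <- as_distance_matrix(d)
  dx0 <- as_probe_distances(dx0, nrow(dm), arg = "dx0")
  geom <- between_group_distances(dm, pert)
  phi2 <- proximity(dx0, pert, geom$variabilities)
  inca_statistic(phi2, geom)
}

#' Allocate a typical unit to a cluster
#'
#' A unit judged typical is allocated to the cluster with the smallest
#' projection \eqn{U_j(g_0) = \hat\phi^2_j(g_0) - W(g_0)}: the squared
#' in-hyperplane distance towards cluster j. Ties go to the
#' smallest cluster index.
#'
#' @param stat an `"inca_stat"` object or a numeric vector of projections U.
#' @return Integer index of the allocated cluster (named when group labels
#'   are available).
#' @examples
#' allocate(c(137.9698, 137.3148, 7.615953))   # 3
#' @export
allocate <- function(stat) {
  U <- if (inherits(stat, "inca_stat")) stat$U else as.numeric(stat)
  if (length(U) == 0 || anyNA(U)) stop("no valid projections to allocate from", call. = FALSE)
  i <- which.min(U)  # which.min takes the first minimum: ties to smallest index
  if (!is.null(names(U))) i <- setNames(i, names(U)[i])
  i
}

#' @export
print.inca_stat <- function(x, ...) {
  cat("INCA statistic\n")
  cat("  W =", format(x$W), if (x$degenerate) " (degenerate: centres span the space)" else "", "\n")
  cat("  U projections:", paste(format(x$U), collapse = "  "), "\n")
  invisible(x)
}

#' @export
print.group_geometry <- function(x, ...) {
  cat("Group geometry for", length(x$variabilities), "groups\n")
  cat("  geometric variabilities:\n")
  print(x$variabilities)
  cat("  squared between-group distances:\n")
  print(x$delta2)
  invisible(x)
}

# Batched INCA statistic: W for many probe units against one partition.
# D2ref: n x n squared distances among reference units; labels: 1..k ints;
# D2cross: n x m squared distances from the n reference units to m probes.
# Shares one Lagrange system across probes (it depends only on delta2).
batch_w <- function(D2ref, labels, D2cross) {
  k <- max(labels)
  n <- nrow(D2ref)
  v <- vapply(seq_len(k), function(j) {
    idx <- labels == j
    sum(D2ref[idx, idx]) / (2 * sum(idx)^2)
  }, numeric(1))
  phi2 <- vapply(seq_len(k), function(j) {
    colMeans(D2cross[labels == j, , drop = FALSE]) - v[j]
  }, numeric(ncol(D2cross)))          # m x k
  phi2 <- matrix(phi2, ncol = k)
  if (k == 1) return(drop(phi2))
  delta2 <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      a <- labels == i; b <- labels == j
      delta2[i, j] <- delta2[j, i] <- mean(D2ref[a, b]) - v[i] - v[j]
    }
  }
  M <- rbind(cbind(delta2, 1), c(rep(1, k), 0))
  B <- rbind(t(phi2), 1)              # (k+1) x m
  X <- tryCatch(solve(M, B), error = function(e) MASS::ginv(M) %*% B)
  A <- X[seq_len(k), , drop = FALSE]  # k x m weight vectors
  W <- colSums(A * t(phi2)) - 0.5 * colSums(A * (delta2 %*% A))
  # same floor policy as inca_statistic(): absorb floating-point negatives,
  # keep genuinely negative heights from non-Euclidean dissimilarities
  tiny <- -1e-8 * max(abs(phi2), 1)
  W[W < 0 & W > tiny] <- 0
  W
}
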