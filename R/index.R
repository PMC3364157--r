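#' INCA index of a fixed partition
#'
#' Measures how credible a partition into k clusters is. For each cluster
#' \eqn{C_j}, the INCA statistic \eqn{W_{C_j}(g)} of every unit g is
#' computed with respect to the remaining clusters \eqn{\{C_i : i \neq j\}};
#' the cutoff \eqn{\bar W_{C_j}} is the maximum over the units outside
#' \eqn{C_j}. A member of \eqn{C_j} is well classified when its height
#' strictly exceeds that cutoff -- it stands further from the hyperplane of
#' the other clusters than any unit that actually lives near it. With
#' \eqn{N_j} well-classified members out of \eqn{n_j},
#' \deqn{INCA_k = \frac{1}{k} \sum_{j=1}^k \frac{N_j}{n_j} \in [0, 1].}
#' Values near 1 back the partition; low flat values across k signal no
#' cluster structure. For k = 2 the reduced reference holds a single
#' cluster, so \eqn{W_{C_j}(g)} collapses to the proximity
#' \eqn{\hat\phi^2(g, C_i)}.
#'
#' Units that belong to a reference cluster are scored with their distances
#' as-is, zero self-distance included: the statistic depends only on the
#' distance matrix and the labels, not on unit identity.
#'
#' @inheritParams geometric_variability
#' @param pert partition labels (k >= 2 groups).
#' @return An object of class `"inca_index"`: list with `well_class`
#'   (\eqn{N_j}), `sizes` (\eqn{n_j}), `thresholds` (\eqn{\bar W_{C_j}}),
#'   `total` (the index, a proportion in \eqn{[0, 1]}), `k` and `groups`.
#' @examples
#' set.seed(1)
#' pts <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 8), 10))
#' inca_index(dist(pts), rep(1:2, each = 10))
#' @seealso [inca_curve()] to scan k, [estimate_k()] for the decision rule
#' @export
inca_index <- function(d, pert) {
  dm <- as_distance_matrix(d)
  part <- as_partition(pert, nrow(dm))
  if (part$k < 2) stop("'pert' must define at least two groups", call. = FALSE)
  D2 <- dm^2
  k <- part$k
  Nj <- integer(k)
  thr <- numeric(k)
  for (j in seq_len(k)) {
    ref <- part$labels != j
    # reduced labels 1..k-1 over the reference units
    rl <- part$labels[ref]
    rl <- match(rl, sort(unique(rl)))
    W <- batch_w(D2[ref, ref, drop = FALSE], rl, D2[ref, , drop = FALSE])
    thr[j] <- max(W[ref])
    Nj[j] <- sum(W[!ref] > thr[j])
  }
  structure(list(well_class = setNames(Nj, part$groups),
                 sizes = setNames(part$sizes, part$groups),
                 thresholds = setNames(thr, part$groups),
                 total = mean(Nj / part$sizes),
                 k = k, groups = part$groups),
            class = "inca_index")
}

#' @export
print.inca_index <- function(x, ...) {
  cat("INCA index for a partition into", x$k, "clusters\n")
  tab <- data.frame(cluster = x$groups, size = as.integer(x$sizes),
                    well_classified = as.integer(x$well_class),
                    percent = round(100 * x$well_class / x$sizes, 2))
  print(tab, row.names = FALSE)
  cat(sprintf("Total well classified (INCA index): %.2f%%\n", 100 * x$total))
  invisible(x)
}

#' @export
summary.inca_index <- function(object, ...) {
  structure(list(total = object$total,
                 percent = setNames(100 * object$well_class / object$sizes,
                                    object$groups)),
            class = "summary.inca_index")
}

#' @export
print.summary.inca_index <- function(x, ...) {
  cat(sprintf("Percentage of units well classified: %.2f%%\n", 100 * x$total))
  invisible(x)
}

#' @describeIn inca_index bar chart of per-cluster well-classified percentages.
#' @param x an `"inca_index"` object.
#' @param ... further arguments passed to [graphics::barplot()].
#' @export
plot.inca_index <- function(x, ...) {
  barplot(100 * x$well_class / x$sizes, names.arg = x$groups,
          ylab = "% well classified", xlab = "cluster", ylim = c(0, 100), ...)
  invisible(x)
}
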