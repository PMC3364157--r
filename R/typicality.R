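#' Bootstrap typicality test for a new unit
#'
#' Tests whether a new unit \eqn{g_0}, described by its distances to the n
#' reference units, is typical of the fixed partition (null hypothesis) or
#' atypical, i.e. drawn from a different and unknown cluster. The test
#' statistic is the INCA statistic \eqn{W(g_0)} -- the squared height of
#' \eqn{g_0} above the hyperplane through the cluster centres. Its null
#' distribution is rarely tractable, in particular for mixed data, so it is
#' bootstrapped: `np` units are drawn with replacement from the pooled
#' reference units and their W values form an empirical null; this is
#' repeated `10 * P` times. A repetition rejects when the empirical
#' p-value \eqn{p = \#\{W_b \ge W(g_0)\} / np} falls below `alpha`
#' (`estimator = "plus_one"` uses \eqn{(1 + \#)/(np + 1)} instead). The
#' reported `pct_under_alpha` is the percentage of rejecting repetitions;
#' the unit is declared atypical when it reaches
#' `100 * atypical_threshold`, and is otherwise allocated to the cluster
#' with the smallest projection \eqn{U_j}.
#'
#' Resampled units are scored with their distance rows as-is (zero
#' self-distance included), and the pool is all n units -- including any
#' unit identical to \eqn{g_0} that may sit in the reference set.
#'
#' @inheritParams geometric_variability
#' @param pert partition labels of the n reference units.
#' @param d_test numeric vector of length n: distances from \eqn{g_0} to
#'   the reference units, in the order of the distance matrix.
#' @param np bootstrap sample size per repetition (default 1000).
#' @param alpha significance level of each repetition's test, in (0, 1).
#' @param P repetition multiplier: the bootstrap is repeated `10 * P` times.
#' @param seed optional integer; when given, repetition r uses a seed
#'   derived from `(seed, r)` so results are exactly reproducible.
#' @param estimator `"plain"` for \eqn{\#/np} (default) or `"plus_one"` for
#'   the \eqn{(1+\#)/(np+1)} p-value estimator.
#' @param atypical_threshold fraction of rejecting repetitions (default
#'   0.5) at which the verdict becomes "atypical".
#' @return An object of class `"inca_test"`: list with `W0`, `U`, `alpha`,
#'   `np`, `P`, `rejections`, `pct_under_alpha`, `verdict` (`"typical"` or
#'   `"atypical"`), `allocated` (cluster index, `NA` when atypical), `seed`
#'   and `groups`.
#' @examples
#' set.seed(7)
#' pts <- rbind(matrix(rnorm(40, 0, .3), 20), matrix(rnorm(40, 5, .3), 20))
#' d <- as.matrix(dist(pts))
#' probe <- c(20, 20)   # far from both clusters
#' d0 <- sqrt(colSums((t(pts) - probe)^2))
#' inca_test(d, rep(1:2, each = 20), d0, np = 200, seed = 1)
#' @export
inca_test <- function(d, pert, d_test, np = 1000, alpha = 0.05, P = 1,
                      seed = NULL, estimator = c("plain", "plus_one"),
                      atypical_threshold = 0.5) {
  estimator <- match.arg(estimator)
  dm <- as_distance_matrix(d)
  n <- nrow(dm)
  part <- as_partition(pert, n)
  d_test <- as_probe_distances(d_test, n)
  if (!is.numeric(np) || np < 1) stop("'np' must be a positive integer", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(P) || P < 1) stop("'P' must be a positive integer", call. = FALSE)
  np <- as.integer(np); P <- as.integer(P)

  D2 <- dm^2
  geom <- between_group_distances(dm, part$labels)
  phi2 <- proximity(d_test, part$labels, geom$variabilities)
  stat <- inca_statistic(phi2, geom)

  # in-sample W of every reference unit (n distinct values); resampling then
  # only indexes into them
  W_ref <- batch_w(D2, part$labels, D2)

  reps <- 10L * P
  rejections <- 0L
  for (r in seq_len(reps)) {
    if (!is.null(seed)) set.seed(rep_seed(seed, r))
    Wb <- W_ref[sample.int(n, np, replace = TRUE)]
    p <- if (estimator == "plain") {
      sum(Wb >= stat$W) / np
    } else {
      (1 + sum(Wb >= stat$W)) / (np + 1)
    }
    if (p < alpha) rejections <- rejections + 1L
  }
  pct <- 100 * rejections / reps
  verdict <- if (pct >= 100 * atypical_threshold) "atypical" else "typical"
  structure(list(W0 = stat$W, U = stat$U, alpha = alpha, np = np, P = P,
                 rejections = rejections, pct_under_alpha = pct,
                 verdict = verdict,
                 allocated = if (verdict == "typical") allocate(stat) else NA_integer_,
                 degenerate = stat$degenerate,
                 seed = seed, groups = part$groups),
            class = "inca_test")
}

# Independent substream seed for repetition r; kept within 32-bit range.
rep_seed <- function(seed, r) {
  (as.integer(seed) %% 1000003L) * 2011L + 7919L * as.integer(r)
}

#' @export
print.inca_test <- function(x, ...) {
  cat("INCA test\n")
  cat("INCA statistic value =", format(x$W0), "\n")
  cat("U projections values:\n")
  for (j in seq_along(x$U)) {
    cat(sprintf("U%s = %s\n", x$groups[j], format(x$U[[j]])))
  }
  cat(sprintf("significative tests for alpha= %g: %d (of %d repetitions, %.4g%%)\n",
              x$alpha, x$rejections, 10 * x$P, x$pct_under_alpha))
  if (x$verdict == "atypical") {
    cat("Verdict: atypical (candidate for a new cluster)\n")
  } else {
    cat(sprintf("Verdict: typical; allocated to cluster %s\n",
                x$groups[x$allocated]))
  }
  invisible(x)
}
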