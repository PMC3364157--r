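# Distance constructors. Units are rows of every input table; all functions
# return a symmetric matrix with zero diagonal and the row names as unit ids.

#' Bhattacharyya distance between frequency profiles
#'
#' For two units carrying frequency vectors \eqn{(p_{i1},...,p_{im})} and
#' \eqn{(p_{j1},...,p_{jm})} the distance is
#' \deqn{d(i,j) = \arccos \sum_{l=1}^m \sqrt{p_{il} p_{jl}},}
#' the angle between the square-root profiles on the unit sphere, taking
#' values in \eqn{[0, \pi/2]}.
#'
#' @param x numeric matrix or data frame of frequencies, one unit per row;
#'   entries must be non-negative and each row must sum to 1 (tolerance 1e-8).
#' @return Symmetric distance matrix with the row names of `x` as unit ids.
#' @examples
#' p <- rbind(a = c(0.25, 0.75), b = c(0.75, 0.25))
#' dist_bhattacharyya(p)["a", "b"]   # pi/6
#' @export
dist_bhattacharyya <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be numeric frequencies", call. = FALSE)
  if (anyNA(x)) stop("'x' contains missing frequencies", call. = FALSE)
  neg <- which(apply(x, 1, function(r) any(r < 0)))
  if (length(neg)) {
    stop(sprintf("negative frequencies in row %s", .row_id(x, neg[1L])), call. = FALSE)
  }
  bad <- which(abs(rowSums(x) - 1) > 1e-8)
  if (length(bad)) {
    stop(sprintf("row %s does not sum to 1 (sum = %.10g)",
                 .row_id(x, bad[1L]), rowSums(x)[bad[1L]]), call. = FALSE)
  }
  sq <- sqrt(x)
  coef <- tcrossprod(sq)
  coef <- pmin(pmax(coef, 0), 1)
  d <- acos(coef)
  diag(d) <- 0
  .with_ids(d, x)
}

#' Gower distance for mixed variables with missing values
#'
#' Units described by \eqn{m_1} continuous, \eqn{m_2} binary
#' (presence/absence) and \eqn{m_3} qualitative variables are compared with
#' Gower's similarity coefficient
#' \deqn{s_{ij} = \frac{\sum_{l=1}^{m_1} (1 - |x_{il} - x_{jl}| / R_l)
#'   + a + \alpha}{m_1 + (m_2 - d) + m_3},}
#' where \eqn{R_l} is the range of the l-th continuous variable, \eqn{a} and
#' \eqn{d} count presence-presence and absence-absence matches among the
#' binary variables, and \eqn{\alpha} counts matching states among the
#' qualitative variables. The distance is \eqn{d_{ij} = \sqrt{2 (1 - s_{ij})}},
#' which is Euclidean-embeddable. When either unit has a missing value in a
#' variable, that variable is dropped from both the numerator and its
#' denominator contribution for the pair (Gower's weighted coefficient), so
#' incomplete records remain comparable as long as at least one variable is
#' shared.
#'
#' A constant continuous variable (\eqn{R_l = 0}) contributes a full match
#' (1) to the numerator, the limit of \eqn{1 - |\Delta x| / R} for identical
#' values.
#'
#' @param x data frame or matrix of observations, one unit per row. Factors
#'   and character columns are treated as qualitative, logical columns as
#'   binary; numeric columns default to continuous.
#' @param types optional character vector, one entry per column, overriding
#'   the inferred kinds; values in `"continuous"`, `"binary"`,
#'   `"qualitative"`. Binary columns must contain only 0/1 (1 = presence).
#' @return Symmetric distance matrix \eqn{d_{ij} = \sqrt{2(1 - s_{ij})}}.
#' @examples
#' x <- data.frame(b1 = c(1, 0), b2 = c(1, 0))
#' dist_gower(x, types = c("binary", "binary"))[1, 2]   # sqrt(2)
#' @export
dist_gower <- function(x, types = NULL) {
  if (is.matrix(x)) x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!is.data.frame(x)) stop("'x' must be a data frame or matrix", call. = FALSE)
  n <- nrow(x)
  m <- ncol(x)
  if (n < 2) stop("'x' needs at least two units", call. = FALSE)
  if (is.null(types)) {
    types <- vapply(x, function(col) {
      if (is.factor(col) || is.character(col)) "qualitative"
      else if (is.logical(col)) "binary"
      else "continuous"
    }, character(1))
  }
  types <- match.arg(types, c("continuous", "binary", "qualitative"), several.ok = TRUE)
  if (length(types) != m) {
    stop(sprintf("'types' has length %d but 'x' has %d columns", length(types), m),
         call. = FALSE)
  }
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (l in seq_len(m)) {
    col <- x[[l]]
    obs <- !is.na(col)
    both <- outer(obs, obs, "&")
    if (types[l] == "continuous") {
      v <- as.numeric(col)
      rng <- if (any(obs)) diff(range(v[obs])) else 0
      if (rng > 0) {
        diffs <- abs(outer(v, v, "-")) / rng
        diffs[!both] <- 0
        num <- num + both * (1 - diffs)
      } else {
        num <- num + both  # constant variable: identical values, full match
      }
      den <- den + both
    } else if (types[l] == "binary") {
      v <- as.numeric(col)
      if (any(!(v[obs] %in% c(0, 1)))) {
        stop(sprintf("binary column %s contains values other than 0/1",
                     .col_id(x, l)), call. = FALSE)
      }
      pres <- outer(v == 1, v == 1, "&") & both          # presence-presence
      absent <- outer(v == 0, v == 0, "&") & both        # absence-absence
      num <- num + pres
      den <- den + (both & !absent)  # each binary variable counts unless absence-absence
    } else {
      eq <- outer(as.character(col), as.character(col), "==") & both
      num <- num + eq
      den <- den + both
    }
  }
  offdiag_zero <- which(den == 0 & row(den) != col(den), arr.ind = TRUE)
  if (nrow(offdiag_zero)) {
    stop(sprintf("units %s and %s share no comparable variable",
                 .row_id(x, offdiag_zero[1, 1]), .row_id(x, offdiag_zero[1, 2])),
         call. = FALSE)
  }
  s <- num / den
  diag(s) <- 1  # self-similarity, even when every self-term is absence-absence
  if (any(s < -1e-8) || any(s > 1 + 1e-8)) {
    stop("internal error: Gower similarity outside [0, 1]", call. = FALSE)
  }
  s <- pmin(pmax(s, 0), 1)
  d <- sqrt(2 * (1 - s))
  diag(d) <- 0
  d <- (d + t(d)) / 2
  .with_ids(d, x)
}

#' Pairwise Mahalanobis distances
#'
#' Squared distance \eqn{d^2(i,j) = (x_i - x_j)^\top S^{-} (x_i - x_j)}
#' between every pair of rows, with \eqn{S} the covariance matrix of the
#' full table and \eqn{S^{-}} its Moore-Penrose pseudo-inverse when singular
#' (eigenvalues below `1e-10` times the largest are dropped). Unlike
#' [stats::mahalanobis()], which measures distances to a fixed centre, this
#' compares units to each other. The distance is invariant under invertible
#' affine transformations of the columns.
#'
#' @param x numeric matrix or data frame of continuous observations, one
#'   unit per row, at least two rows.
#' @return Symmetric distance matrix (square roots of the quadratic form).
#' @export
dist_mahalanobis <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x)) stop("'x' must be complete numeric data", call. = FALSE)
  if (nrow(x) < 2) stop("'x' needs at least two units", call. = FALSE)
  S <- cov(x)
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > 1e-10 * max(e$values, 0)
  if (!any(keep)) stop("'x' has zero variance in every direction", call. = FALSE)
  # project onto the whitened retained directions; Euclidean distance there
  # realises the pseudo-inverse quadratic form
  Y <- x %*% e$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(e$values[keep]),
                                                      nrow = sum(keep))
  d <- as.matrix(dist(Y))
  .with_ids(d, x)
}

#' Correlation distance between unit profiles
#'
#' Pearson correlation \eqn{r_{ij}} between the profiles (rows) of two
#' units, mapped to a distance. The default transform
#' \eqn{d_{ij} = \sqrt{2 (1 - r_{ij})}} (range \eqn{[0, 2]}) is
#' Euclidean-embeddable -- it is the Euclidean distance between the
#' standardized profiles up to a constant factor -- which keeps all the
#' height-based statistics non-negative. The simpler \eqn{d = 1 - r} is
#' available via `method = "one_minus_r"`.
#'
#' @param x numeric matrix or data frame, one unit profile per row; every
#'   row must have non-zero variance.
#' @param method `"sqrt"` for \eqn{\sqrt{2(1 - r)}} (default) or
#'   `"one_minus_r"` for \eqn{1 - r}.
#' @return Symmetric distance matrix.
#' @export
dist_correlation <- function(x, method = c("sqrt", "one_minus_r")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x)) stop("'x' must be complete numeric data", call. = FALSE)
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    stop(sprintf("unit %s has a constant profile: correlation undefined",
                 .row_id(x, which(sds == 0)[1L])), call. = FALSE)
  }
  r <- cor(t(x))
  r <- pmin(pmax(r, -1), 1)
  d <- if (method == "sqrt") sqrt(2 * (1 - r)) else 1 - r
  diag(d) <- 0
  d <- (d + t(d)) / 2
  .with_ids(d, x)
}

.row_id <- function(x, i) {
  if (!is.null(rownames(x))) rownames(x)[i] else as.character(i)
}
.col_id <- function(x, j) {
  if (!is.null(colnames(x))) colnames(x)[j] else as.character(j)
}
.with_ids <- function(d, x) {
  ids <- if (!is.null(rownames(x))) rownames(x) else as.character(seq_len(nrow(d)))
  dimnames(d) <- list(ids, ids)
  d
}
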