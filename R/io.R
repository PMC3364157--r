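# Readers and writers for the delimited formats the command-line interface
# exchanges: square distance matrices, partition label files, mixed data
# tables with a variable-kind side-car, and probe distance vectors.
# CSV and TSV are told apart by file extension (.tsv/.tab/.txt = tab).

.read_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  sep <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
  read.table(path, header = TRUE, sep = sep, check.names = FALSE,
             stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

.write_table <- function(df, path, row_names = FALSE) {
  sep <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
  write.table(df, path, sep = sep, quote = FALSE, row.names = row_names,
              col.names = TRUE)
}

#' Read a square distance matrix from a delimited file
#'
#' Expects a header row and a first column of unit ids matching it; the
#' body must be square, symmetric (within 1e-8; tiny asymmetries are
#' averaged away with a warning), non-negative, with a zero diagonal.
#'
#' @param path CSV (or TSV, by extension) file path.
#' @return Validated numeric distance matrix with unit ids as dimnames.
#' @seealso [write_distance_matrix()]
#' @export
read_distance_matrix <- function(path) {
  df <- .read_table(path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) {
    stop(sprintf("'%s' is not square: %d rows, %d value columns", path, nrow(m), ncol(m)),
         call. = FALSE)
  }
  rownames(m) <- ids
  if (!identical(colnames(m), ids)) {
    if (setequal(colnames(m), ids)) m <- m[, ids, drop = FALSE]
    else stop(sprintf("'%s': column ids do not match row ids", path), call. = FALSE)
  }
  as_distance_matrix(m, arg = path)
}

#' @rdname read_distance_matrix
#' @param d distance matrix or `dist` object to write.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as_distance_matrix(d)
  # full 17-digit formatting so a write -> read round trip is bit-exact
  chr <- apply(m, 2, function(col) sprintf("%.17g", col))
  df <- data.frame(id = rownames(m), chr, check.names = FALSE)
  .write_table(df, path)
  invisible(path)
}

#' Read or write a partition label file
#'
#' Two columns: unit id and a positive integer cluster label. Labels with
#' gaps (e.g. 1, 3, 4) are remapped to consecutive integers with a warning.
#'
#' @param path CSV/TSV file path.
#' @return Named integer vector of labels in 1..k.
#' @export
read_partition_file <- function(path) {
  df <- .read_table(path)
  if (ncol(df) < 2) stop(sprintf("'%s' must have an id column and a label column", path),
                         call. = FALSE)
  part <- as_partition(df[[2]], nrow(df), arg = path)
  setNames(part$labels, as.character(df[[1]]))
}

#' @rdname read_partition_file
#' @param labels named (or plain) label vector to write.
#' @export
write_partition_file <- function(labels, path) {
  ids <- if (!is.null(names(labels))) names(labels) else as.character(seq_along(labels))
  .write_table(data.frame(id = ids, cluster = as.integer(labels)), path)
  invisible(path)
}

#' Read a mixed-variable data table with a variable-kind side-car
#'
#' The main file holds one unit per row with an id first column; missing
#' entries are empty fields or `NA`. The side-car declares one of
#' `continuous`, `binary` or `qualitative` for every variable column (two
#' columns: variable name, kind).
#'
#' @param path data table file.
#' @param kinds_path side-car file; `NULL` infers kinds from column types.
#' @return Data frame with unit ids as row names and a `"types"` attribute,
#'   ready for [dist_gower()].
#' @export
read_mixed_table <- function(path, kinds_path = NULL) {
  df <- .read_table(path)
  ids <- as.character(df[[1]])
  x <- df[, -1, drop = FALSE]
  rownames(x) <- ids
  if (!is.null(kinds_path)) {
    kinds <- .read_table(kinds_path)
    if (ncol(kinds) < 2) {
      stop(sprintf("'%s' must have two columns: variable name, kind", kinds_path),
           call. = FALSE)
    }
    idx <- match(colnames(x), as.character(kinds[[1]]))
    if (anyNA(idx)) {
      stop(sprintf("no declared kind for variable '%s'", colnames(x)[is.na(idx)][1L]),
           call. = FALSE)
    }
    types <- match.arg(as.character(kinds[[2]])[idx],
                       c("continuous", "binary", "qualitative"), several.ok = TRUE)
    attr(x, "types") <- types
  }
  x
}

#' Read probe-to-reference distances
#'
#' One value column (optionally preceded by a unit-id column aligned with
#' the distance matrix ids).
#'
#' @param path CSV/TSV file path.
#' @param ids optional reference unit ids to align/validate against.
#' @return Numeric vector of distances.
#' @export
read_probe_distances <- function(path, ids = NULL) {
  df <- .read_table(path)
  vals <- if (ncol(df) >= 2) setNames(as.numeric(df[[2]]), as.character(df[[1]]))
          else as.numeric(df[[1]])
  if (!is.null(ids) && !is.null(names(vals))) {
    if (!setequal(names(vals), ids)) {
      stop(sprintf("'%s': probe distance ids do not match the distance matrix", path),
           call. = FALSE)
    }
    vals <- vals[ids]
  }
  if (!is.null(ids) && length(vals) != length(ids)) {
    stop(sprintf("'%s' has %d distances but there are %d reference units",
                 path, length(vals), length(ids)), call. = FALSE)
  }
  vals
}
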