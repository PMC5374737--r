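#' Construct a feature matrix
#'
#' A `hocus_features` object is a samples-by-features integer matrix with
#' unique sample ids as row names and unique feature ids as column names.
#' Binary matrices (mutation presence, voxel masks) hold values in `{0, 1}`;
#' ordinal matrices (gene-level thresholded copy-number calls) hold integer
#' values in `{-2, -1, 0, 1, 2}`.
#'
#' @param values Numeric matrix, samples in rows, features in columns. Row and
#'   column names are required and must be unique.
#' @param kind `"binary"` or `"ordinal"`.
#' @return A `hocus_features` object (a matrix with a `kind` attribute).
#' @examples
#' m <- matrix(c(1, 0, 1, 1), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("TP53", "KRAS")))
#' feature_matrix(m, "binary")
#' @export
feature_matrix <- function(values, kind = c("binary", "ordinal")) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry sample ids (rownames) and feature ids (colnames)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate feature ids", call. = FALSE)
  if (nrow(values) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (ncol(values) < 1L) stop("need at least 1 feature", call. = FALSE)
  storage.mode(values) <- "integer"
  if (anyNA(values)) stop("missing values are not allowed", call. = FALSE)
  allowed <- if (kind == "binary") 0:1 else -2:2
  bad <- !(values %in% allowed)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(values)), arr.ind = TRUE)[1L, ]
    stop(sprintf("value %d at sample '%s', feature '%s' outside %s range",
                 values[idx[1L], idx[2L]], rownames(values)[idx[1L]],
                 colnames(values)[idx[2L]], kind), call. = FALSE)
  }
  structure(values, kind = kind, class = c("hocus_features", "matrix", "array"))
}

#' @export
print.hocus_features <- function(x, ...) {
  cat(sprintf("<hocus_features> %d samples x %d features (%s)\n",
              nrow(x), ncol(x), attr(x, "kind")))
  cat(sprintf("  events: %d (density %.3f)\n", sum(x != 0L),
              mean(x != 0L)))
  invisible(x)
}

#' @export
as_tibble.hocus_features <- function(x, ...) {
  tibble::as_tibble(as.data.frame(unclass(x)), rownames = "sample")
}

sample_ids <- function(x) rownames(x)
feature_ids <- function(x) colnames(x)

#' Write / read a feature matrix as TSV
#'
#' Plain tab-separated text with sample ids in the first column (`sample`)
#' and feature ids as the header. The `kind` is stored in a `# kind:` comment
#' on the first line so a round trip reproduces the object exactly.
#'
#' @param x A `hocus_features` object.
#' @param path File path.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` returns a `hocus_features` object.
#' @export
write_feature_matrix <- function(x, path) {
  stopifnot(inherits(x, "hocus_features"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# kind: ", attr(x, "kind")), con)
  writeLines(paste(c("sample", colnames(x)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], x[i, ]), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @param kind Matrix kind; if `NULL` (default) taken from the `# kind:`
#'   header comment, falling back to `"binary"`.
#' @export
read_feature_matrix <- function(path, kind = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(kind)) {
    kind <- if (grepl("^# kind:", first)) sub("^# kind:\\s*", "", first) else "binary"
  }
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  feature_matrix(m, kind = kind)
}
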