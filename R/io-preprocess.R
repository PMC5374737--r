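#' Variant classes treated as non-silent
#'
#' Protein-altering classes retained for mutation subtyping: missense,
#' nonsense, splice-site, insertions and deletions. Matching against MAF
#' variant classifications is case-insensitive, normalizes spaces and hyphens
#' to underscores, and strips a trailing `_mutation`/`_variant` suffix, so
#' `"Splice_Site"`, `"splice-site"` and `"Splice_Site_Mutation"` all match.
#'
#' @return Character vector of normalized class names.
#' @export
nonsilent_classes <- function() {
  c("missense", "nonsense", "splice_site", "insertion", "deletion")
}

# Classes that are recognized MAF vocabulary but not protein-altering; they
# are filtered silently rather than flagged as unknown.
silent_classes <- function() {
  c("silent", "synonymous", "intron", "3'utr", "5'utr", "utr", "igr", "rna",
    "flank", "5'flank", "3'flank", "noncoding")
}

normalize_variant_class <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[ -]", "_", x)
  sub("_(mutation|variant)$", "", x)
}

#' Read a MAF-like mutation table
#'
#' Minimal tab-separated mutation call table with one row per called variant.
#' Column names are configurable because MAF dialects differ.
#'
#' @param path Path to a TSV file.
#' @param sample_col,gene_col,class_col Column names holding the sample
#'   barcode, gene symbol and variant classification.
#' @return A tibble with columns `sample`, `gene`, `variant_class`.
#' @export
read_maf <- function(path, sample_col = "sample", gene_col = "gene",
                     class_col = "variant_classification") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  missing <- setdiff(c(sample_col, gene_col, class_col), names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(sample = as.character(df[[sample_col]]),
                 gene = as.character(df[[gene_col]]),
                 variant_class = as.character(df[[class_col]]))
}

#' Build a binary mutation matrix from a mutation call table
#'
#' Retains only non-silent calls, then encodes presence: a cell is 1 iff the
#' sample carries at least one retained mutation in that gene. Genes with no
#' retained mutation and samples with no retained mutation do not appear in
#' the output, so the matrix has no all-zero row or column. Multiple calls in
#' the same sample/gene collapse to a single 1.
#'
#' @param table Tibble/data frame with columns `sample`, `gene`,
#'   `variant_class` (see [read_maf()]).
#' @param nonsilent Normalized variant classes to retain
#'   (default [nonsilent_classes()]).
#' @param unknown What to do with variant classes outside the declared
#'   vocabulary: `"skip"` (default; drops them with a warning) or `"error"`.
#' @return A binary `hocus_features` matrix. Samples and genes appear in
#'   order of first appearance in `table`.
#' @examples
#' calls <- tibble::tibble(
#'   sample = c("s1", "s1", "s2", "s2", "s3"),
#'   gene = c("TP53", "TTN", "TP53", "KRAS", "EGFR"),
#'   variant_class = c("Missense", "Silent", "Nonsense", "Splice_Site", "Silent"))
#' build_mutation_matrix(calls)
#' @export
build_mutation_matrix <- function(table, nonsilent = nonsilent_classes(),
                                  unknown = c("skip", "error")) {
  unknown <- match.arg(unknown)
  table <- tibble::as_tibble(table)
  stopifnot(all(c("sample", "gene", "variant_class") %in% names(table)))
  if (nrow(table) == 0L) stop("mutation table is empty", call. = FALSE)
  if (length(nonsilent) == 0L) stop("`nonsilent` must be non-empty", call. = FALSE)
  if (any(!nzchar(table$sample)) || any(!nzchar(table$gene))) {
    stop("empty sample or gene identifiers", call. = FALSE)
  }
  cls <- normalize_variant_class(table$variant_class)
  known <- c(normalize_variant_class(nonsilent), silent_classes())
  unk <- !(cls %in% known)
  if (any(unk)) {
    msg <- sprintf("%d record(s) with unrecognized variant class: %s",
                   sum(unk), paste(unique(table$variant_class[unk]), collapse = ", "))
    if (unknown == "error") stop(msg, call. = FALSE)
    warning(msg, ", skipped", call. = FALSE)
  }
  keep <- cls %in% normalize_variant_class(nonsilent)
  retained <- table[keep, , drop = FALSE]
  if (nrow(retained) == 0L) {
    stop("no non-silent mutation records remain after filtering", call. = FALSE)
  }
  samples <- unique(retained$sample)
  genes <- unique(retained$gene)
  mat <- matrix(0L, length(samples), length(genes),
                dimnames = list(samples, genes))
  mat[cbind(match(retained$sample, samples), match(retained$gene, genes))] <- 1L
  feature_matrix(mat, "binary")
}

#' Read a GISTIC-style ordinal copy-number matrix
#'
#' Gene-level thresholded copy-number calls with integer values in
#' `{-2, -1, 0, 1, 2}` (deep/shallow deletion, neutral, low/high
#' amplification). Any non-integer or out-of-range cell is a parse error that
#' names the offending row and column.
#'
#' @param path TSV with ids in the first column and the other dimension in
#'   the header.
#' @param samples Orientation on disk: `"rows"` (default) or `"cols"`
#'   (matrix is transposed after reading, for Firehose-style gene-rows files).
#' @return An ordinal `hocus_features` matrix.
#' @export
read_ordinal_matrix <- function(path, samples = c("rows", "cols")) {
  samples <- match.arg(samples)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- is.na(v) | v != round(v) | v < -2 | v > 2
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("invalid copy-number value '%s' at row '%s', column '%s'",
                   vals[[j]][i], ids[i], names(vals)[j]), call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  if (samples == "cols") m <- t(m)
  feature_matrix(m, "ordinal")
}

#' Voxel mask sets
#'
#' A `voxel_mask_set` holds per-sample 3-D binary tumor masks registered to a
#' shared grid, the form produced by upstream delineation and atlas
#' registration of MR images.
#'
#' @param masks Named list of 3-D `{0,1}` arrays, all with identical
#'   dimensions.
#' @return A `voxel_mask_set` (list with elements `masks` and `dim`).
#' @export
voxel_mask_set <- function(masks) {
  if (!length(masks)) stop("no masks supplied", call. = FALSE)
  if (is.null(names(masks)) || anyDuplicated(names(masks))) {
    stop("masks must be uniquely named by sample id", call. = FALSE)
  }
  dims <- lapply(masks, dim)
  if (any(vapply(dims, length, 1L) != 3L)) {
    stop("masks must be 3-D arrays", call. = FALSE)
  }
  if (!all(vapply(dims, identical, TRUE, dims[[1L]]))) {
    stop("all masks must share identical grid dimensions", call. = FALSE)
  }
  masks <- lapply(masks, function(a) {
    storage.mode(a) <- "integer"
    if (!all(a %in% 0:1)) stop("mask values must be 0/1", call. = FALSE)
    a
  })
  structure(list(masks = masks, dim = dims[[1L]]), class = "voxel_mask_set")
}

#' @export
print.voxel_mask_set <- function(x, ...) {
  cat(sprintf("<voxel_mask_set> %d masks on a %s grid\n", length(x$masks),
              paste(x$dim, collapse = "x")))
  invisible(x)
}

# Voxel ids in row-major order over (x, y, z): z varies fastest. The fixed
# ordering makes flattened matrices reproducible across runs.
voxel_ids <- function(dim) {
  g <- expand.grid(z = seq_len(dim[3]), y = seq_len(dim[2]), x = seq_len(dim[1]))
  sprintf("v_%d_%d_%d", g$x, g$y, g$z)
}

#' Flatten voxel masks and keep informative voxels
#'
#' Flattens each 3-D mask to a row of a binary samples-by-voxels matrix and
#' retains only informative voxels: those containing tumor in some, but not
#' all, of the patients. A voxel with tumor count `c` over `m` samples is
#' kept iff `min_count <= c <= m - 1`.
#'
#' @param masks A [voxel_mask_set()].
#' @param min_count Minimum number of individuals with tumor at a voxel for
#'   it to be informative (default 15).
#' @return A binary `hocus_features` matrix whose feature ids encode the
#'   `(x, y, z)` grid coordinates.
#' @export
flatten_and_filter_voxels <- function(masks, min_count = 15L) {
  stopifnot(inherits(masks, "voxel_mask_set"), min_count >= 1L)
  m <- length(masks$masks)
  flat <- t(vapply(masks$masks,
                   function(a) as.integer(aperm(a, c(3L, 2L, 1L))),
                   integer(prod(masks$dim))))
  colnames(flat) <- voxel_ids(masks$dim)
  counts <- colSums(flat)
  keep <- counts >= min_count & counts <= m - 1L
  if (!any(keep)) {
    stop("no informative voxels: none with tumor count in [", min_count,
         ", ", m - 1L, "]", call. = FALSE)
  }
  feature_matrix(flat[, keep, drop = FALSE], "binary")
}

#' Write / read voxel masks as a packed coordinate TSV
#'
#' One row per grid voxel with `x`, `y`, `z` coordinate columns followed by
#' one 0/1 column per sample.
#'
#' @param masks A [voxel_mask_set()].
#' @param path File path.
#' @export
write_voxel_masks <- function(masks, path) {
  stopifnot(inherits(masks, "voxel_mask_set"))
  g <- expand.grid(z = seq_len(masks$dim[3]), y = seq_len(masks$dim[2]),
                   x = seq_len(masks$dim[1]))
  df <- data.frame(x = g$x, y = g$y, z = g$z)
  for (s in names(masks$masks)) {
    df[[s]] <- as.integer(aperm(masks$masks[[s]], c(3L, 2L, 1L)))
  }
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_voxel_masks
#' @export
read_voxel_masks <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("x", "y", "z") %in% names(df)))
  dims <- c(max(df$x), max(df$y), max(df$z))
  df <- df[order(df$x, df$y, df$z), , drop = FALSE]
  samples <- setdiff(names(df), c("x", "y", "z"))
  masks <- lapply(samples, function(s) {
    a <- array(0L, dims)
    a[cbind(df$x, df$y, df$z)] <- as.integer(df[[s]])
    a
  })
  names(masks) <- samples
  voxel_mask_set(masks)
}
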