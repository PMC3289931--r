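# Library-size normalization and the virtual reference library.
#
# Every library is rescaled to a fixed tag total (100,000 by convention) so
# that "cluster sizes" — per-tag or per-gene counts — are comparable across
# libraries of different sequencing depth.  Counts are kept fractional; the
# z-test operates on raw counts with true totals, normalization is for
# reporting and clustering.

.extract_counts <- function(x) {
  if (inherits(x, "tag_library")) {
    list(counts = x$counts, id = x$library_id, total = x$total_tags)
  } else if (inherits(x, "gene_counts")) {
    list(counts = x$counts, id = x$library_id, total = sum(x$counts))
  } else if (inherits(x, "normalized_library")) {
    list(counts = x$counts, id = x$library_id, total = sum(x$counts))
  } else if (is.numeric(x) && !is.null(names(x))) {
    list(counts = x, id = "library", total = sum(x))
  } else {
    stop("cannot interpret object as a count library", call. = FALSE)
  }
}

#' Normalize a library to a fixed tag total
#'
#' Multiplies every count by \code{target / total} so the library sums to
#' \code{target}.  Values are kept real-valued (no rounding).  The operation
#' is idempotent: normalizing an already-normalized library to the same
#' target is a no-op.
#'
#' @param x a \code{\link{tag_library}}, \code{gene_counts} object,
#'   \code{normalized_library}, or named numeric count vector.
#' @param target normalized total, default 100000.
#' @param library_id optional identifier override.
#' @return an object of class \code{normalized_library}: list with
#'   \code{library_id}, \code{counts} (named numeric), \code{target_size},
#'   \code{source_total} (pre-normalization total), \code{virtual} flag.
#' @export
normalize_library <- function(x, target = 1e5, library_id = NULL) {
  stopifnot(is.numeric(target), target > 0)
  ex <- .extract_counts(x)
  if (ex$total <= 0) stop("empty library: total count is 0", call. = FALSE)
  source_total <- if (inherits(x, "normalized_library")) x$source_total
                  else ex$total
  structure(list(library_id = if (is.null(library_id)) ex$id else library_id,
                 counts = ex$counts * (target / ex$total),
                 target_size = target,
                 source_total = source_total,
                 virtual = FALSE),
            class = "normalized_library")
}

#' @export
print.normalized_library <- function(x, ...) {
  cat(if (x$virtual) "virtual " else "", "normalized library '",
      x$library_id, "': ", length(x$counts), " keys, total ",
      format(sum(x$counts)), " (target ", format(x$target_size), ")\n",
      sep = "")
  invisible(x)
}

#' Build a virtual library by per-key averaging of two normalized libraries
#'
#' The key set is the union of the two inputs; a key missing from one library
#' is averaged against zero (i.e. halved).  Halving singletons is the only
#' convention that conserves totals: the virtual total equals the mean of the
#' input totals, hence equals the common target when both inputs are fully
#' normalized.
#'
#' @param a,b \code{normalized_library} objects with equal
#'   \code{target_size}.
#' @param library_id identifier of the virtual library; defaults to
#'   \code{"virtual(<a>+<b>)"}.
#' @return a \code{normalized_library} with \code{virtual = TRUE}.
#' @export
make_virtual_library <- function(a, b, library_id = NULL) {
  stopifnot(inherits(a, "normalized_library"),
            inherits(b, "normalized_library"))
  if (abs(a$target_size - b$target_size) >
      1e-9 * max(a$target_size, b$target_size)) {
    stop("libraries normalized to different targets (",
         a$target_size, " vs ", b$target_size, ")", call. = FALSE)
  }
  keys <- union(names(a$counts), names(b$counts))
  va <- vb <- setNames(numeric(length(keys)), keys)
  va[names(a$counts)] <- a$counts
  vb[names(b$counts)] <- b$counts
  if (is.null(library_id)) {
    library_id <- sprintf("virtual(%s+%s)", a$library_id, b$library_id)
  }
  structure(list(library_id = library_id,
                 counts = (va + vb) / 2,
                 target_size = a$target_size,
                 source_total = NA_integer_,
                 virtual = TRUE),
            class = "normalized_library")
}

#' Read/write normalized libraries as TSV
#'
#' Same dialect as the tag-count tables: \code{key<TAB>value}, sorted by
#' descending value then key.  The JSON sidecar flags virtual libraries.
#'
#' @param lib a \code{normalized_library}.
#' @param path output TSV path.
#' @param sidecar write JSON sidecar (default TRUE).
#' @return \code{path}, invisibly.
#' @export
write_normalized_library <- function(lib, path, sidecar = TRUE) {
  stopifnot(inherits(lib, "normalized_library"))
  ord <- order(-lib$counts, names(lib$counts))
  df <- data.frame(key = names(lib$counts)[ord],
                   value = unname(lib$counts)[ord])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (sidecar) {
    jsonlite::write_json(list(library_id = lib$library_id,
                              target_size = lib$target_size,
                              source_total = lib$source_total,
                              virtual = lib$virtual,
                              total = sum(lib$counts)),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Assemble a library-by-gene expression matrix
#'
#' @param libs list of \code{normalized_library} / \code{gene_counts} objects
#'   or named numeric vectors; list names override library ids.
#' @param scale \code{"normalized"} or \code{"raw"}; recorded as an
#'   attribute.
#' @return numeric matrix, libraries in rows, union of genes in columns
#'   (missing entries 0), with attribute \code{scale}.
#' @export
build_expression_table <- function(libs, scale = c("normalized", "raw")) {
  scale <- match.arg(scale)
  ex <- lapply(libs, .extract_counts)
  ids <- if (!is.null(names(libs)) && all(nzchar(names(libs)))) names(libs)
         else vapply(ex, `[[`, character(1), "id")
  genes <- sort(unique(unlist(lapply(ex, function(e) names(e$counts)))))
  mat <- matrix(0, nrow = length(libs), ncol = length(genes),
                dimnames = list(ids, genes))
  for (i in seq_along(ex)) mat[i, names(ex[[i]]$counts)] <- ex[[i]]$counts
  attr(mat, "scale") <- scale
  mat
}
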