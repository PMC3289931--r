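# Hierarchical clustering of libraries on correlation distance.
#
# Libraries are compared on their (normalized) per-gene count vectors over
# the genes passing the expression filter; distance is 1 - Pearson
# correlation ("standard correlation"), agglomeration is average linkage by
# default (configurable; the original software's rule is not documented).

#' Correlation distance between expression libraries
#'
#' Genes are filtered to those with count >= \code{min_count} in at least one
#' library (\code{filter = "any"}, the "cluster size >= 2" convention) or in
#' every library (\code{"all"}); distance is \code{1 - cor} between the
#' filtered library vectors, hence in [0, 2].
#'
#' @param table libraries-by-genes numeric matrix
#'   (\code{\link{build_expression_table}}).
#' @param min_count expression filter threshold, default 2.
#' @param filter \code{"any"} (default) or \code{"all"}.
#' @return a \code{dist} object over the libraries.
#' @export
correlation_distance <- function(table, min_count = 2,
                                 filter = c("any", "all")) {
  filter <- match.arg(filter)
  stopifnot(is.matrix(table), nrow(table) >= 2)
  keep <- if (filter == "any") {
    apply(table >= min_count, 2L, any)
  } else {
    apply(table >= min_count, 2L, all)
  }
  if (sum(keep) < 2L) {
    stop("fewer than 2 genes pass the expression filter", call. = FALSE)
  }
  sub <- table[, keep, drop = FALSE]
  sds <- apply(sub, 1L, sd)
  if (any(sds == 0)) {
    stop("constant expression vector; correlation undefined for library: ",
         paste(rownames(sub)[sds == 0], collapse = ", "), call. = FALSE)
  }
  as.dist(1 - cor(t(sub)))
}

#' Agglomerative hierarchical clustering of libraries
#'
#' @param distances a \code{dist} object (e.g. from
#'   \code{\link{correlation_distance}}).
#' @param linkage \code{"average"} (default), \code{"complete"} or
#'   \code{"single"}.
#' @return object of class \code{library_dendrogram}: list with the
#'   \code{hclust} fit, the \code{cophenetic} distance matrix, the
#'   \code{newick} serialization (branch lengths from merge heights) and the
#'   \code{linkage} used.
#' @export
hierarchical_cluster <- function(distances,
                                 linkage = c("average", "complete",
                                             "single")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(distances, "dist"))
  hc <- hclust(distances, method = linkage)
  coph <- as.matrix(cophenetic(hc))
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc,
                 cophenetic = coph,
                 newick = ape::write.tree(phy),
                 linkage = linkage,
                 leaves = hc$labels),
            class = "library_dendrogram")
}

#' @export
print.library_dendrogram <- function(x, ...) {
  cat("library dendrogram (", x$linkage, " linkage, ", length(x$leaves),
      " leaves):\n  ", x$newick, "\n", sep = "")
  invisible(x)
}

#' The pair of libraries farthest apart in the dendrogram
#'
#' Maximal cophenetic distance; ties are broken lexicographically on the
#' sorted pair of library ids.
#'
#' @param dendro a \code{library_dendrogram}.
#' @return character vector of length 2, sorted.
#' @export
farthest_pair <- function(dendro) {
  stopifnot(inherits(dendro, "library_dendrogram"))
  cm <- dendro$cophenetic
  stopifnot(nrow(cm) >= 2)
  mx <- max(cm)
  idx <- which(cm == mx, arr.ind = TRUE)
  pairs <- unique(t(apply(idx, 1L, function(ij)
    sort(c(rownames(cm)[ij[1L]], colnames(cm)[ij[2L]])))))
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  as.character(pairs[1L, ])
}

#' Write a distance matrix to TSV
#'
#' @param distances \code{dist} object or square matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_distance_matrix <- function(distances, path) {
  m <- as.matrix(distances)
  df <- data.frame(library = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
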