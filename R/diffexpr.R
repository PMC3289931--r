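# Differential expression between SAGE libraries.
#
# Tag (or per-gene) counts in two libraries are compared as two binomial
# proportions with the pooled two-proportion z-test (the classical test for
# SAGE count data): with p_a = c_a/n_a, p_b = c_b/n_b and pooled
# p0 = (c_a + c_b)/(n_a + n_b),
#
#   z = (p_a - p_b) / sqrt(p0 (1 - p0) (1/n_a + 1/n_b)).
#
# z^2 is exactly the 1-df Pearson chi-square statistic of the 2x2 table
# (no continuity correction), which the test suite uses as an independent
# oracle.  The test is valid for fractional "counts" too (the virtual
# reference library is an average), in which case n is the normalization
# target.

#' Two-proportion z-test on tag counts
#'
#' @param c_a,c_b counts in libraries a and b (vectorized; may be fractional
#'   for averaged virtual libraries).
#' @param n_a,n_b library totals.
#' @return list with numeric vectors \code{z} and \code{p} (two-sided).
#'   Entries where both counts are zero are non-testable and returned as
#'   \code{NA}.
#' @examples
#' ztest_counts(10, 1e5, 0, 1e5)  # z ~ 3.162
#' @export
ztest_counts <- function(c_a, n_a, c_b, n_b) {
  stopifnot(all(n_a > 0), all(n_b > 0),
            all(c_a >= 0), all(c_b >= 0),
            all(c_a <= n_a), all(c_b <= n_b))
  p_a <- c_a / n_a
  p_b <- c_b / n_b
  p0 <- (c_a + c_b) / (n_a + n_b)
  se <- sqrt(p0 * (1 - p0) * (1 / n_a + 1 / n_b))
  z <- ifelse(p_a == p_b, 0, (p_a - p_b) / se)
  p <- 2 * pnorm(-abs(z))
  none <- (c_a + c_b) == 0
  z[none] <- NA_real_
  p[none] <- NA_real_
  list(z = z, p = p)
}

.counts_and_total <- function(x) {
  if (inherits(x, "normalized_library")) {
    list(counts = x$counts, n = x$target_size, id = x$library_id)
  } else {
    ex <- .extract_counts(x)
    list(counts = ex$counts, n = ex$total, id = ex$id)
  }
}

#' Pairwise differential expression between two libraries
#'
#' The tested universe is the set of genes expressed (count >=
#' \code{min_count}) in the reference library \code{lib_a}; each is compared
#' against its count in \code{lib_b} (0 if absent).  Genes expressed in a and
#' entirely absent from b are additionally flagged \code{unique_to = "a"}.
#'
#' @param lib_a,lib_b per-gene count libraries (\code{gene_counts},
#'   \code{tag_library}, \code{normalized_library} or named numeric vector).
#'   For raw libraries the true sequencing totals are used as n; a
#'   \code{normalized_library} contributes its target size.
#' @param alpha two-sided significance level, default 0.05 (no
#'   multiple-testing correction by default).
#' @param min_count expression threshold defining the universe, default 2.
#' @param p_adjust \code{"none"} (default) or \code{"BH"}.
#' @return data.frame with one row per universe gene: \code{gene_id},
#'   \code{count_a}, \code{count_b}, \code{n_a}, \code{n_b},
#'   \code{proportion_a}, \code{proportion_b}, \code{z}, \code{p},
#'   \code{direction} (\code{up_in_a}/\code{down_in_a}/\code{equal}),
#'   \code{significant}, \code{unique_to} (\code{a}/\code{none}).
#' @export
pairwise_de <- function(lib_a, lib_b, alpha = 0.05, min_count = 2,
                        p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(alpha >= 0, alpha <= 1)
  a <- .counts_and_total(lib_a)
  b <- .counts_and_total(lib_b)
  universe <- names(a$counts)[a$counts >= min_count]
  c_a <- unname(a$counts[universe])
  c_b <- setNames(numeric(length(universe)), universe)
  in_b <- intersect(universe, names(b$counts))
  c_b[in_b] <- b$counts[in_b]
  c_b <- unname(c_b)
  zt <- ztest_counts(c_a, a$n, c_b, b$n)
  p_use <- if (p_adjust == "BH") stats::p.adjust(zt$p, method = "BH")
           else zt$p
  prop_a <- c_a / a$n
  prop_b <- c_b / b$n
  res <- data.frame(
    gene_id = universe,
    count_a = c_a, count_b = c_b,
    n_a = a$n, n_b = b$n,
    proportion_a = prop_a, proportion_b = prop_b,
    z = zt$z, p = zt$p,
    direction = ifelse(prop_a > prop_b, "up_in_a",
                       ifelse(prop_a < prop_b, "down_in_a", "equal")),
    significant = !is.na(p_use) & p_use < alpha,
    unique_to = ifelse(c_b == 0, "a", "none"),
    stringsAsFactors = FALSE)
  attr(res, "library_a") <- a$id
  attr(res, "library_b") <- b$id
  attr(res, "alpha") <- alpha
  attr(res, "min_count") <- min_count
  res[order(res$gene_id), , drop = FALSE]
}

#' Consistently differentially expressed genes across all case libraries
#'
#' A gene qualifies as upregulated when it is expressed (count >=
#' \code{min_count}) in every case (metastatic) library and is significantly
#' higher than the reference in the case-vs-reference z-test — in every
#' individual comparison under \code{consistency = "per_library"}, or on
#' pooled case counts under \code{"pooled"}.  Genes expressed in all case
#' libraries but entirely absent from the reference are counted as
#' upregulated and flagged unique.  The rule for downregulation is symmetric
#' (reference present, all case comparisons significantly lower).
#'
#' @param case_libs named list of raw per-gene count libraries (one per
#'   metastatic library).
#' @param reference a \code{normalized_library} (typically the virtual
#'   non-metastatic library) or any count library; its counts may be
#'   fractional.
#' @param alpha significance level per comparison, default 0.05.
#' @param min_count expression threshold, default 2.
#' @param consistency \code{"per_library"} (default) or \code{"pooled"}.
#' @return object of class \code{consistent_de_set}: list with
#'   \code{up_genes}, \code{down_genes} (character vectors, disjoint),
#'   \code{unique_genes} (subset of \code{up_genes}, absent from the
#'   reference), \code{per_comparison} (long data.frame of every z-test), and
#'   the parameters used.
#' @export
consistent_de <- function(case_libs, reference, alpha = 0.05, min_count = 2,
                          consistency = c("per_library", "pooled")) {
  consistency <- match.arg(consistency)
  stopifnot(length(case_libs) >= 2)
  cases <- lapply(case_libs, .counts_and_total)
  ref <- .counts_and_total(reference)
  ids <- if (!is.null(names(case_libs)) && all(nzchar(names(case_libs)))) {
    names(case_libs)
  } else vapply(cases, `[[`, character(1), "id")

  expressed <- lapply(cases, function(x) names(x$counts)[x$counts >= min_count])
  universe <- sort(Reduce(intersect, expressed))
  if (length(universe) == 0L) {
    return(structure(list(up_genes = character(0), down_genes = character(0),
                          unique_genes = character(0),
                          per_comparison = NULL, alpha = alpha,
                          min_count = min_count, consistency = consistency),
                     class = "consistent_de_set"))
  }
  cmat <- vapply(cases, function(x) {
    v <- setNames(numeric(length(universe)), universe)
    hit <- intersect(universe, names(x$counts))
    v[hit] <- x$counts[hit]
    v
  }, numeric(length(universe)))
  totals <- vapply(cases, `[[`, numeric(1), "n")
  ref_counts <- setNames(numeric(length(universe)), universe)
  hit <- intersect(universe, names(ref$counts))
  ref_counts[hit] <- ref$counts[hit]

  absent_ref <- ref_counts == 0
  per <- NULL
  if (consistency == "per_library") {
    zl <- lapply(seq_along(ids), function(i) {
      zt <- ztest_counts(cmat[, i], totals[i], ref_counts, ref$n)
      data.frame(gene_id = universe, library = ids[i],
                 count_case = unname(cmat[, i]),
                 count_ref = unname(ref_counts),
                 z = zt$z, p = zt$p, stringsAsFactors = FALSE)
    })
    per <- do.call(rbind, zl)
    zmat <- vapply(zl, function(d) d$z, numeric(length(universe)))
    pmat <- vapply(zl, function(d) d$p, numeric(length(universe)))
    sig_up <- rowSums(pmat < alpha & zmat > 0, na.rm = TRUE) == length(ids) &
      apply(pmat, 1L, function(p) all(!is.na(p)))
    sig_down <- rowSums(pmat < alpha & zmat < 0, na.rm = TRUE) == length(ids) &
      apply(pmat, 1L, function(p) all(!is.na(p)))
  } else {
    zt <- ztest_counts(rowSums(cmat), sum(totals), ref_counts, ref$n)
    per <- data.frame(gene_id = universe, library = "pooled",
                      count_case = unname(rowSums(cmat)),
                      count_ref = unname(ref_counts),
                      z = zt$z, p = zt$p, stringsAsFactors = FALSE)
    sig_up <- !is.na(zt$p) & zt$p < alpha & zt$z > 0
    sig_down <- !is.na(zt$p) & zt$p < alpha & zt$z < 0
  }

  up <- universe[absent_ref | (!absent_ref & sig_up)]
  down <- universe[!absent_ref & sig_down]
  structure(list(up_genes = up,
                 down_genes = down,
                 unique_genes = universe[absent_ref],
                 per_comparison = per,
                 alpha = alpha, min_count = min_count,
                 consistency = consistency,
                 case_ids = ids, reference_id = ref$id),
            class = "consistent_de_set")
}

#' @export
print.consistent_de_set <- function(x, ...) {
  cat("consistent DE set vs '", x$reference_id, "': ",
      length(x$up_genes), " up (", length(x$unique_genes),
      " unique to cases), ", length(x$down_genes), " down; alpha = ",
      x$alpha, ", ", x$consistency, "\n", sep = "")
  invisible(x)
}

#' Cluster-size bias of differentially expressed genes
#'
#' Compares the mean expression level ("cluster size", i.e. tag count) of
#' significantly differentially expressed genes against that of genes with no
#' significant difference, optionally restricted to a gene subset.
#'
#' @param counts named numeric vector of (normalized) per-gene counts.
#' @param de_flags named logical vector over the same genes: TRUE for
#'   significantly differentially expressed.
#' @param subset optional character vector restricting the computation.
#' @return list with \code{mean_de}, \code{mean_non_de} (NA when a group is
#'   empty), \code{n_de}, \code{n_non_de}.
#' @export
cluster_size_bias <- function(counts, de_flags, subset = NULL) {
  stopifnot(!is.null(names(counts)), !is.null(names(de_flags)))
  genes <- intersect(names(counts), names(de_flags))
  if (!is.null(subset)) genes <- intersect(genes, subset)
  fl <- de_flags[genes]
  cn <- counts[genes]
  list(mean_de = if (any(fl)) mean(cn[fl]) else NA_real_,
       mean_non_de = if (any(!fl)) mean(cn[!fl]) else NA_real_,
       n_de = sum(fl), n_non_de = sum(!fl))
}

#' Write a pairwise DE table to TSV
#'
#' @param res data.frame from \code{\link{pairwise_de}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_de_table <- function(res, path) {
  write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
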