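# Set algebra of expressed, common, multifunctional and biased gene sets.
#
# The "multifunctional grid" is the set of genes belonging to at least two of
# eight metastasis-relevant functional categories.  Intersecting the grid
# with the genes commonly expressed in the metastatic libraries gives the
# metastatic multifunctional signature; intersecting with the reference
# (non-metastatic) expressed set gives its counterpart; the subset of the
# metastatic signature that is consistently differentially (or uniquely)
# expressed is the "biased" multifunctional signature.

#' Default metastasis-relevant functional category names
#' @export
metastasis_category_names <- c("cell motility", "cell adhesion", "chemotaxis",
                               "blood coagulation", "cell proliferation",
                               "ECM remodeling", "angiogenesis",
                               "antiapoptosis")

#' Construct a functional-category annotation
#'
#' @param sets named list of character vectors (category name to gene set).
#'   Sets may overlap.
#' @param category_names required category names; defaults to the eight
#'   metastasis-relevant categories.  Every configured name must be present
#'   (possibly empty) and no others.
#' @return object of class \code{functional_categories}.
#' @export
functional_categories <- function(sets,
                                  category_names = metastasis_category_names) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  missing <- setdiff(category_names, names(sets))
  extra <- setdiff(names(sets), category_names)
  if (length(missing) || length(extra)) {
    stop("category names must be exactly the configured set; missing: ",
         paste(missing, collapse = ", "), "; unexpected: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  sets <- lapply(sets[category_names], function(g) unique(as.character(g)))
  structure(list(categories = sets), class = "functional_categories")
}

#' @export
print.functional_categories <- function(x, ...) {
  cat("functional categories:\n")
  for (nm in names(x$categories)) {
    cat("  ", nm, ": ", length(x$categories[[nm]]), " genes\n", sep = "")
  }
  invisible(x)
}

#' Read a functional-category annotation from TSV
#'
#' TSV with columns \code{gene_id} and \code{category} (header optional).
#'
#' @param path TSV file.
#' @inheritParams functional_categories
#' @return a \code{functional_categories} object.
#' @export
read_categories <- function(path,
                            category_names = metastasis_category_names) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character",
                   col.names = c("gene_id", "category"))
  if (identical(tolower(df$gene_id[1L]), "gene_id")) {
    df <- df[-1L, , drop = FALSE]
  }
  sets <- split(df$gene_id, df$category)
  for (nm in setdiff(category_names, names(sets))) sets[[nm]] <- character(0)
  functional_categories(sets, category_names = category_names)
}

#' Read a gene list (one gene per line)
#'
#' @param path text file.
#' @return character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Genes expressed in a library
#'
#' @param lib a count library (any form accepted by the package).
#' @param min_count expression threshold, default 2 (the "cluster size >= 2"
#'   convention).
#' @return character vector of gene ids with count >= \code{min_count}.
#' @export
expressed_genes <- function(lib, min_count = 2) {
  ex <- .extract_counts(lib)
  names(ex$counts)[ex$counts >= min_count]
}

#' Genes expressed in every library
#'
#' @param libs list of count libraries.
#' @inheritParams expressed_genes
#' @return character vector: intersection of the per-library expressed sets.
#' @export
common_genes <- function(libs, min_count = 2) {
  stopifnot(length(libs) >= 2)
  sort(Reduce(intersect, lapply(libs, expressed_genes,
                                min_count = min_count)))
}

#' Per-gene category membership counts
#'
#' @param categories a \code{functional_categories} object.
#' @return named integer vector: number of categories each gene belongs to.
#' @export
category_membership <- function(categories) {
  stopifnot(inherits(categories, "functional_categories"))
  all_genes <- unlist(categories$categories, use.names = FALSE)
  if (!length(all_genes)) return(setNames(integer(0), character(0)))
  tab <- table(unlist(lapply(categories$categories, unique),
               use.names = FALSE))
  setNames(as.integer(tab), names(tab))
}

#' The multifunctional grid
#'
#' Genes belonging to at least \code{min_categories} of the functional
#' categories.
#'
#' @inheritParams category_membership
#' @param min_categories membership threshold, default 2.
#' @return character vector of gene ids, sorted.
#' @export
build_grid <- function(categories, min_categories = 2L) {
  m <- category_membership(categories)
  sort(names(m)[m >= min_categories])
}

#' Format a percentage the way the report prints it
#'
#' \code{100 * numerator / denominator}, rounded half-up to \code{digits}
#' decimal places (so 158/1488 prints 10.6 and 27/74 prints 36 at 0 digits).
#'
#' @param numerator,denominator non-negative numbers.
#' @param digits decimal places, default 1.
#' @return numeric percentage (NA if the denominator is 0).
#' @export
format_percent <- function(numerator, denominator, digits = 1L) {
  if (any(denominator == 0)) {
    out <- rep(NA_real_, length(numerator))
    ok <- denominator != 0
    out[ok] <- format_percent(numerator[ok], denominator[ok], digits)
    return(out)
  }
  v <- 100 * numerator / denominator
  f <- 10^digits
  floor(v * f + 0.5) / f
}

#' Build the full signature report
#'
#' Computes the nested set algebra: metastatic multifunctional signature
#' (grid intersected with the commonly expressed metastatic genes),
#' non-metastatic signature (grid intersected with the reference expressed
#' set), the unique/shared partition of their union, and the biased
#' multifunctional signature (signature members that are consistently
#' differentially or uniquely expressed).  Inclusion-exclusion on the
#' combined set is computed from the parts and checked.
#'
#' @param common_met character vector: genes expressed in every metastatic
#'   library.
#' @param nm_expressed character vector: genes expressed in the reference
#'   (non-metastatic) condition.
#' @param grid character vector: the multifunctional grid
#'   (\code{\link{build_grid}}).
#' @param de a \code{consistent_de_set} from \code{\link{consistent_de}}.
#' @param mean_expression optional named numeric vector of mean normalized
#'   expression (averaged over the metastatic libraries) used to annotate
#'   subsets.
#' @return object of class \code{signature_report}: list with the gene sets
#'   \code{common_met}, \code{nm_expressed}, \code{grid},
#'   \code{met_signature}, \code{nm_signature}, \code{combined},
#'   \code{unique_met}, \code{unique_nm}, \code{shared}; the
#'   \code{biased_signature} data.frame (\code{gene_id}, \code{status} in
#'   \{\code{up_differential}, \code{down_differential}, \code{unique_met}\});
#'   \code{percentages} (biased/met_signature and combined identity check);
#'   \code{mean_expression} annotations per subset.
#' @export
build_signature_report <- function(common_met, nm_expressed, grid, de,
                                   mean_expression = NULL) {
  stopifnot(inherits(de, "consistent_de_set"))
  common_met <- unique(as.character(common_met))
  nm_expressed <- unique(as.character(nm_expressed))
  grid <- unique(as.character(grid))
  if (!length(grid)) warning("empty multifunctional grid", call. = FALSE)

  met_signature <- sort(intersect(grid, common_met))
  nm_signature <- sort(intersect(grid, nm_expressed))
  combined <- sort(union(met_signature, nm_signature))
  shared <- sort(intersect(met_signature, nm_signature))
  unique_met <- sort(setdiff(met_signature, nm_signature))
  unique_nm <- sort(setdiff(nm_signature, met_signature))

  de_genes <- union(de$up_genes, de$down_genes)
  biased_genes <- sort(intersect(met_signature, de_genes))
  status <- ifelse(biased_genes %in% de$unique_genes, "unique_met",
                   ifelse(biased_genes %in% de$up_genes, "up_differential",
                          "down_differential"))
  biased <- data.frame(gene_id = biased_genes, status = status,
                       stringsAsFactors = FALSE)

  subset_mean <- function(genes) {
    if (is.null(mean_expression) || !length(genes)) return(NA_real_)
    mean(mean_expression[intersect(genes, names(mean_expression))])
  }
  report <- structure(list(
    common_met = sort(common_met),
    nm_expressed = sort(nm_expressed),
    grid = sort(grid),
    met_signature = met_signature,
    nm_signature = nm_signature,
    combined = combined,
    unique_met = unique_met,
    unique_nm = unique_nm,
    shared = shared,
    biased_signature = biased,
    percentages = list(
      biased_of_met_signature = format_percent(nrow(biased),
                                               length(met_signature)),
      de_of_common = format_percent(length(intersect(de_genes, common_met)),
                                    length(common_met))),
    inclusion_exclusion_ok =
      length(combined) == length(met_signature) + length(nm_signature) -
        length(shared),
    mean_expression = list(
      met_signature = subset_mean(met_signature),
      nm_signature = subset_mean(nm_signature),
      unique_met = subset_mean(unique_met),
      unique_nm = subset_mean(unique_nm),
      shared = subset_mean(shared),
      biased = subset_mean(biased_genes))),
    class = "signature_report")
  report
}

#' @export
print.signature_report <- function(x, ...) {
  cat("signature report\n",
      "  common (cases):        ", length(x$common_met), "\n",
      "  expressed (reference): ", length(x$nm_expressed), "\n",
      "  multifunctional grid:  ", length(x$grid), "\n",
      "  case signature:        ", length(x$met_signature), "\n",
      "  reference signature:   ", length(x$nm_signature), "\n",
      "  combined:              ", length(x$combined),
      " (", length(x$unique_met), " unique-case, ", length(x$unique_nm),
      " unique-reference, ", length(x$shared), " shared)\n",
      "  biased signature:      ", nrow(x$biased_signature), " (",
      sum(x$biased_signature$status == "unique_met"), " unique, ",
      sum(x$biased_signature$status == "up_differential"), " up, ",
      sum(x$biased_signature$status == "down_differential"), " down)\n",
      sep = "")
  invisible(x)
}

#' Overlap of an external gene list with every signature set
#'
#' Used for e.g. the metastasis-associated literature list and the
#' ribosomal-protein annotation.
#'
#' @param report a \code{signature_report}.
#' @param gene_list character vector of gene ids.
#' @param label label for the list.
#' @return data.frame with columns \code{label}, \code{set},
#'   \code{set_size}, \code{list_size}, \code{overlap}.
#' @export
annotate_subset <- function(report, gene_list, label = "list") {
  stopifnot(inherits(report, "signature_report"))
  gene_list <- unique(as.character(gene_list))
  sets <- list(common_met = report$common_met,
               nm_expressed = report$nm_expressed,
               grid = report$grid,
               met_signature = report$met_signature,
               nm_signature = report$nm_signature,
               combined = report$combined,
               unique_met = report$unique_met,
               unique_nm = report$unique_nm,
               shared = report$shared,
               biased_signature = report$biased_signature$gene_id)
  data.frame(label = label,
             set = names(sets),
             set_size = vapply(sets, length, integer(1)),
             list_size = length(gene_list),
             overlap = vapply(sets, function(s)
               length(intersect(s, gene_list)), integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read the printed biased-signature validation table
#'
#' Parses a TSV with columns \code{gene_symbol}, \code{direction}
#' (\code{up}/\code{down}) and \code{unique_met} (\code{TRUE}/\code{FALSE});
#' the packaged copy (\code{system.file("extdata",
#' "biased_signature.tsv", package = "sagesig")}) transcribes the published
#' 15-gene biased multifunctional signature.
#'
#' @param path TSV file; defaults to the packaged table.
#' @return data.frame with those three columns.
#' @export
read_signature_table <- function(path = system.file("extdata",
                                                    "biased_signature.tsv",
                                                    package = "sagesig")) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_symbol", "direction", "unique_met") %in% names(df)))
  df$unique_met <- as.logical(df$unique_met)
  if (anyNA(df$unique_met) || !all(df$direction %in% c("up", "down"))) {
    stop("malformed signature table", call. = FALSE)
  }
  df
}
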