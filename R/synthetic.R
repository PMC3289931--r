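# Synthetic SAGE study generator.
#
# Emulates the structure of a single-patient comparative SAGE study: five
# metastatic libraries and two non-metastatic libraries of 77,000-110,000
# tags each, a shared core of expressed genes, planted fold changes between
# conditions (including genes uniquely expressed in the metastases),
# overlapping functional categories with a target multifunctional grid size,
# and validation qPCR data.  Every draw is seeded and every planted fact is
# recorded in a ground-truth ledger so downstream recovery can be asserted.

#' Default library depths of the emulated study panel
#'
#' Five metastatic and two non-metastatic library sizes (total sequenced
#' tags).
#' @export
panel_depths <- c(Met1 = 87957, Met2 = 108331, Met3 = 109862,
                  Met4 = 83522, Met5 = 88439,
                  NM1 = 77757, NM2 = 77019)

#' Default functional-category sizes
#' @export
panel_category_sizes <- c("cell motility" = 126, "cell adhesion" = 483,
                          "chemotaxis" = 125, "blood coagulation" = 81,
                          "cell proliferation" = 302, "ECM remodeling" = 99,
                          "angiogenesis" = 66, "antiapoptosis" = 118)

#' Generate a transcriptome abundance vector
#'
#' Log-normal relative abundances (the standard heavy-tailed model for
#' transcript frequencies), normalized to sum 1.  \code{sigma = 0} gives
#' uniform abundances.
#'
#' @param n_genes number of genes.
#' @param mu,sigma log-normal parameters (default 0 and 1.5).
#' @param seed integer seed.
#' @param gene_ids optional identifiers; default \code{G0001, G0002, ...}.
#' @return named numeric abundance vector summing to 1.
#' @export
generate_transcriptome <- function(n_genes, mu = 0, sigma = 1.5, seed,
                                   gene_ids = NULL) {
  stopifnot(n_genes >= 1, sigma >= 0)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%04d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  set.seed(as.integer(seed))
  x <- if (sigma == 0) rep(exp(mu), n_genes) else rlnorm(n_genes, mu, sigma)
  setNames(x / sum(x), gene_ids)
}

#' Plant condition-specific expression effects
#'
#' Multiplies selected genes' abundance by \code{fold} (up) or \code{1/fold}
#' (down) in the case condition, and zeroes selected genes in the reference
#' condition (uniquely expressed in cases; these are also raised by
#' \code{fold} in the case condition so their detection does not hinge on a
#' low baseline).  Both vectors are renormalized to sum 1.
#'
#' @param base named abundance vector (\code{\link{generate_transcriptome}}).
#' @param n_up,n_down,n_unique numbers of planted genes per class.
#' @param fold fold change, default 8.
#' @param seed integer seed for the gene selection.
#' @param eligible_up,eligible_down optional candidate gene pools; by default
#'   up/unique genes are drawn from the upper abundance quintile and down
#'   genes from the top 120 most abundant genes (a downregulated gene must
#'   stay comfortably expressed in every case library).
#' @return list with \code{case} and \code{reference} abundance vectors and
#'   \code{ledger}: list(\code{up}, \code{down}, \code{unique}, \code{fold}).
#' @export
plant_effects <- function(base, n_up = 80, n_down = 70, n_unique = 8,
                          fold = 8, seed, eligible_up = NULL,
                          eligible_down = NULL) {
  stopifnot(fold >= 1, n_up + n_down + n_unique <= length(base))
  set.seed(as.integer(seed))
  ord <- names(base)[order(base, decreasing = TRUE)]
  if (is.null(eligible_down)) eligible_down <- head(ord, 120L)
  if (is.null(eligible_up)) {
    eligible_up <- setdiff(head(ord, ceiling(length(base) / 5)),
                           eligible_down)
  }
  down <- if (n_down > 0) sample(eligible_down, n_down) else character(0)
  pool <- setdiff(eligible_up, down)
  stopifnot(length(pool) >= n_up + n_unique)
  pick <- if (n_up + n_unique > 0) sample(pool, n_up + n_unique)
          else character(0)
  up <- pick[seq_len(n_up)]
  unique_genes <- setdiff(pick, up)

  case <- base
  case[c(up, unique_genes)] <- case[c(up, unique_genes)] * fold
  case[down] <- case[down] / fold
  reference <- base
  reference[unique_genes] <- 0
  list(case = case / sum(case),
       reference = reference / sum(reference),
       ledger = list(up = sort(up), down = sort(down),
                     unique = sort(unique_genes), fold = fold))
}

# deterministic tag alphabet: length-10 strings over {A,T,G}.  Tags contain
# no C, their reverse complements contain no G, so the anchoring site CATG
# can occur nowhere inside a ditag -- only at the planted separators.
.sage_tags <- function(n, tag_len = 10L) {
  stopifnot(n <= 3^tag_len)
  bases <- c("A", "T", "G")
  idx <- seq_len(n) - 1L
  out <- matrix("", nrow = n, ncol = tag_len)
  for (p in seq_len(tag_len)) {
    out[, tag_len - p + 1L] <- bases[idx %% 3L + 1L]
    idx <- idx %/% 3L
  }
  apply(out, 1L, paste, collapse = "")
}

#' Build a synthetic tag-to-gene assignment
#'
#' One unique CATG-free 10-mer per gene by default; a fraction of tags can be
#' made ambiguous (mapped to one extra gene) to exercise aggregation
#' policies.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param tag_len tag length, default 10.
#' @param ambiguous_fraction fraction of tags additionally mapped to a second
#'   gene, default 0.
#' @param seed seed for the ambiguous-tag draw (required if
#'   \code{ambiguous_fraction > 0}).
#' @return list with \code{table} (data.frame \code{tag}, \code{gene_id}; one
#'   row per mapping) and \code{map} (a \code{\link{tag_map}}).
#' @export
make_tag_assignment <- function(gene_ids, tag_len = 10L,
                                ambiguous_fraction = 0, seed = NULL) {
  n <- length(gene_ids)
  tags <- .sage_tags(n, tag_len)
  df <- data.frame(tag = tags, gene_id = gene_ids, stringsAsFactors = FALSE)
  if (ambiguous_fraction > 0) {
    stopifnot(!is.null(seed))
    set.seed(as.integer(seed))
    k <- round(ambiguous_fraction * n)
    amb <- sample.int(n, k)
    extra <- data.frame(tag = tags[amb],
                        gene_id = gene_ids[(amb %% n) + 1L],
                        stringsAsFactors = FALSE)
    df <- rbind(df, extra)
  }
  list(table = df, map = tag_map(df$tag, df$gene_id))
}

#' Write a tag-to-gene table to TSV
#' @param assignment result of \code{\link{make_tag_assignment}} (or its
#'   \code{table} data.frame).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tag_assignment <- function(assignment, path) {
  df <- if (is.data.frame(assignment)) assignment else assignment$table
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("tag", "gene_id"))
  invisible(path)
}

#' Simulate a SAGE library by multinomial sampling
#'
#' Draws \code{depth} tags from the gene abundance vector.  With a tag
#' assignment the result is a \code{\link{tag_library}} keyed by tag
#' sequence; without one, a named per-gene integer count vector.
#'
#' @param abundances named abundance vector (sums to 1).
#' @param depth total tags to draw.
#' @param seed integer seed.
#' @param library_id identifier.
#' @param assignment optional result of \code{\link{make_tag_assignment}}
#'   (1:1 tags only are used for the relabeling).
#' @param metadata metadata list for the tag library.
#' @return named numeric gene-count vector, or a \code{tag_library}.
#' @export
simulate_library <- function(abundances, depth, seed, library_id = "synth",
                             assignment = NULL, metadata = list()) {
  stopifnot(depth >= 1, abs(sum(abundances) - 1) < 1e-8)
  set.seed(as.integer(seed))
  draws <- rmultinom(1L, size = depth, prob = abundances)[, 1L]
  counts <- draws[draws > 0]
  if (is.null(assignment)) return(counts)
  tag_of <- setNames(assignment$table$tag[!duplicated(assignment$table$tag)],
                     assignment$table$gene_id[!duplicated(assignment$table$tag)])
  tag_library(setNames(as.numeric(counts), unname(tag_of[names(counts)])),
              library_id = library_id, tag_len = nchar(tag_of[[1L]]),
              metadata = metadata)
}

#' Emit concatemer reads for a tag library
#'
#' Expands the tag counts into a shuffled tag multiset, pairs consecutive
#' tags into ditags (second tag reverse-complemented), optionally plants
#' exact duplicate ditags at \code{duplicate_rate}, and joins ditags into
#' concatemer reads separated (and flanked) by the anchoring site.  An odd
#' leftover tag is dropped and recorded.
#'
#' @param lib a \code{\link{tag_library}}.
#' @param seed integer seed (shuffling, duplicate placement).
#' @param duplicate_rate fraction of ditags duplicated once, default 0.
#' @param ditags_per_read ditags per concatemer read, default 20.
#' @param anchor anchoring site, default CATG.
#' @param path optional FASTA output path.
#' @return list with \code{reads} (named character vector), \code{ledger}:
#'   list(\code{ditags} (pre-duplication), \code{tag_counts_emitted} (the
#'   multiset actually embedded, before deduplication),
#'   \code{tag_counts_post_dedupe} (after collapsing exact duplicate
#'   ditags -- what \code{\link{count_tags}} with \code{dedupe = TRUE}
#'   recovers), \code{n_dropped_odd}, \code{n_duplicates}).
#' @export
emit_concatemers <- function(lib, seed, duplicate_rate = 0,
                             ditags_per_read = 20L, anchor = "CATG",
                             path = NULL) {
  stopifnot(inherits(lib, "tag_library"), duplicate_rate >= 0,
            duplicate_rate < 1)
  set.seed(as.integer(seed))
  tags <- sample(rep(names(lib$counts), times = lib$counts))
  n_drop <- length(tags) %% 2L
  if (n_drop) tags <- tags[-length(tags)]
  first <- tags[c(TRUE, FALSE)]
  second <- tags[c(FALSE, TRUE)]
  ditags <- paste0(first, revcomp(second))
  n_dup <- floor(duplicate_rate * length(ditags))
  emitted <- ditags
  if (n_dup > 0) {
    emitted <- c(ditags, ditags[sample.int(length(ditags), n_dup)])
    emitted <- sample(emitted)
  }
  tally <- function(dt) {
    tb <- table(c(substr(dt, 1L, lib$tag_len),
                  revcomp(substr(dt, nchar(dt) - lib$tag_len + 1L,
                                 nchar(dt)))))
    setNames(as.numeric(tb), names(tb))
  }
  groups <- split(emitted, ceiling(seq_along(emitted) / ditags_per_read))
  reads <- vapply(groups, function(g)
    paste0(anchor, paste(g, collapse = anchor), anchor), character(1))
  names(reads) <- sprintf("%s_read%05d", lib$library_id,
                          seq_along(reads))
  if (!is.null(path)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads), path)
  }
  list(reads = reads,
       ledger = list(ditags = emitted,
                     tag_counts_emitted = tally(emitted),
                     tag_counts_post_dedupe = tally(unique(emitted)),
                     n_dropped_odd = n_drop,
                     n_duplicates = n_dup))
}

#' Generate overlapping functional categories with a known grid
#'
#' Chooses \code{target_grid_size} grid genes (each assigned to exactly two
#' categories, capacity permitting) and fills the remaining category slots
#' with distinct single-category genes, so the set of genes with >= 2
#' memberships is the planted grid exactly.
#'
#' @param gene_ids gene universe.
#' @param sizes named vector of category sizes; default
#'   \code{\link{panel_category_sizes}}.
#' @param target_grid_size planted grid size, default 161.
#' @param seed integer seed.
#' @param force_in_grid genes that must be members of the grid.
#' @param exclude genes excluded from the random part of the grid (forced
#'   genes are still admitted); used to keep planted differential genes out
#'   of the grid unless deliberately placed there.
#' @return list with \code{categories} (a
#'   \code{\link{functional_categories}}), \code{grid} (character vector) and
#'   \code{table} (long data.frame \code{gene_id}, \code{category}).
#' @export
generate_categories <- function(gene_ids, sizes = panel_category_sizes,
                                target_grid_size = 161L, seed,
                                force_in_grid = NULL, exclude = NULL) {
  stopifnot(!is.null(names(sizes)), all(sizes >= 1))
  k <- as.integer(target_grid_size)
  force_in_grid <- unique(as.character(force_in_grid))
  stopifnot(all(force_in_grid %in% gene_ids), length(force_in_grid) <= k)
  n_fill <- sum(sizes) - 2L * k
  if (2L * k > sum(sizes) || k + n_fill > length(gene_ids)) {
    stop("infeasible grid target for the given category sizes and universe",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  grid <- c(force_in_grid,
            sample(setdiff(gene_ids, c(force_in_grid, exclude)),
                   k - length(force_in_grid)))
  remaining <- sizes
  members <- lapply(sizes, function(...) character(0))
  for (g in sample(grid)) {
    open <- names(remaining)[remaining > 0]
    if (length(open) < 2L) {
      stop("infeasible grid target: ran out of category capacity",
           call. = FALSE)
    }
    pick <- sample(open, 2L, prob = remaining[open])
    for (cat in pick) {
      members[[cat]] <- c(members[[cat]], g)
      remaining[cat] <- remaining[cat] - 1L
    }
  }
  fillers <- sample(setdiff(gene_ids, grid), sum(remaining))
  offset <- 0L
  for (cat in names(sizes)) {
    r <- remaining[[cat]]
    if (r > 0) {
      members[[cat]] <- c(members[[cat]], fillers[offset + seq_len(r)])
      offset <- offset + r
    }
  }
  stopifnot(all(vapply(members, length, integer(1)) == sizes))
  categories <- functional_categories(members,
                                      category_names = names(sizes))
  table <- do.call(rbind, lapply(names(members), function(cat)
    data.frame(gene_id = members[[cat]], category = cat,
               stringsAsFactors = FALSE)))
  list(categories = categories, grid = sort(grid), table = table)
}

#' Generate validation qPCR data with known truth
#'
#' Ct values follow \code{Ct = intercept - log(expr) / log(E) + noise} with
#' calibrator expression 1 for every gene and reference-gene expression 1 in
#' every sample; the dilution series is consistent with the planted
#' efficiency.
#'
#' @param ratios genes-by-samples numeric matrix of true expression ratios
#'   versus the calibrator (or a named vector for a single sample).
#' @param efficiencies named per-gene efficiencies, covering the reference
#'   gene; defaults to 2 for every gene.
#' @param ref_gene reference gene id, default \code{"REF18S"}.
#' @param calibrator_id calibrator sample id, default \code{"NMpool"}.
#' @param noise_sd Gaussian Ct noise (cycles), default 0.2.
#' @param n_replicates replicates per reaction, default 3.
#' @param dilution_log10 log10 dilution grid, default \code{0:-4}.
#' @param intercepts optional named per-gene Ct intercepts; default 22.
#' @param seed integer seed.
#' @return list with \code{ct_table}, \code{dilution_table} (data.frames as
#'   read by \code{\link{read_ct_table}} / \code{\link{read_dilution_table}})
#'   and \code{ledger} (ratios, efficiencies, intercepts, noise_sd, seed).
#' @export
generate_qpcr <- function(ratios, efficiencies = NULL, ref_gene = "REF18S",
                          calibrator_id = "NMpool", noise_sd = 0.2,
                          n_replicates = 3L, dilution_log10 = 0:-4,
                          intercepts = NULL, seed) {
  if (is.vector(ratios)) {
    ratios <- matrix(ratios, ncol = 1L,
                     dimnames = list(names(ratios), "sample1"))
  }
  stopifnot(all(ratios > 0), !is.null(rownames(ratios)))
  genes <- c(rownames(ratios), ref_gene)
  if (is.null(efficiencies)) {
    efficiencies <- setNames(rep(2, length(genes)), genes)
  }
  stopifnot(all(genes %in% names(efficiencies)),
            all(efficiencies[genes] > 1), all(efficiencies[genes] <= 2.2))
  if (is.null(intercepts)) {
    intercepts <- setNames(rep(22, length(genes)), genes)
  }
  set.seed(as.integer(seed))
  samples <- colnames(ratios)
  expr <- rbind(cbind(ratios,
                      setNames(data.frame(rep(1, nrow(ratios))),
                               calibrator_id)),
                setNames(data.frame(t(rep(1, length(samples) + 1L))),
                         c(samples, calibrator_id)))
  expr <- as.matrix(expr)
  rownames(expr) <- genes
  rows <- list()
  for (g in genes) {
    for (s in colnames(expr)) {
      ct0 <- intercepts[[g]] -
        log(expr[g, s]) / log(efficiencies[[g]])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, gene_id = g, replicate = seq_len(n_replicates),
        ct = ct0 + rnorm(n_replicates, 0, noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  ct_table <- do.call(rbind, rows)
  dil <- list()
  for (g in genes) {
    dil[[length(dil) + 1L]] <- data.frame(
      gene_id = g, log10_dilution = dilution_log10,
      ct = intercepts[[g]] - dilution_log10 / log10(efficiencies[[g]]) +
        rnorm(length(dilution_log10), 0, noise_sd),
      stringsAsFactors = FALSE)
  }
  list(ct_table = ct_table,
       dilution_table = do.call(rbind, dil),
       ledger = list(ratios = ratios,
                     efficiencies = efficiencies[genes],
                     intercepts = intercepts[genes],
                     ref_gene = ref_gene, calibrator_id = calibrator_id,
                     noise_sd = noise_sd, seed = as.integer(seed)))
}

#' Plant an enriched gene subset
#'
#' Builds a subset of \code{size} genes hitting \code{de_list} at
#' \code{hit_rate} (the remainder drawn from the non-DE part of the
#' universe).
#'
#' @param universe gene universe.
#' @param de_list DE genes, subset of \code{universe}.
#' @param size subset size.
#' @param hit_rate target fraction of the subset inside \code{de_list}.
#' @param seed integer seed.
#' @return list with \code{subset} and \code{ledger} (planted hit count).
#' @export
plant_enriched_subset <- function(universe, de_list, size, hit_rate, seed) {
  stopifnot(all(de_list %in% universe), size <= length(universe),
            hit_rate >= 0, hit_rate <= 1)
  set.seed(as.integer(seed))
  n_hit <- round(size * hit_rate)
  stopifnot(n_hit <= length(de_list),
            size - n_hit <= length(universe) - length(de_list))
  subset <- c(sample(de_list, n_hit),
              sample(setdiff(universe, de_list), size - n_hit))
  list(subset = sample(subset), ledger = list(n_hit = n_hit, size = size))
}

#' Generate a complete study-shaped synthetic scenario
#'
#' Builds the full input set the pipeline consumes: five metastatic and two
#' non-metastatic gene-count libraries at the panel depths, a 1:1
#' tag-to-gene assignment, functional categories with a planted
#' multifunctional grid containing a planted biased signature (7 fold-change
#' genes + all uniquely expressed genes by default), a metastasis-associated
#' gene list with a known grid overlap, and validation qPCR tables.  One of
#' the metastatic libraries is generated with inflated per-library dispersion
#' to act as the expression outlier.
#'
#' Per-library biological variability is modelled as multiplicative
#' log-normal jitter on the condition abundances (sd \code{library_sd} on the
#' log scale; \code{outlier_sd} for the outlier library).
#'
#' @param seed master integer seed; all sub-seeds derive from it.
#' @param n_genes gene-universe size, default 5400 (gives roughly 4,000-4,400
#'   expressed genes per library at the panel depths, the scale of the
#'   emulated study).
#' @param depths named library depths, default \code{\link{panel_depths}}
#'   (first five = cases, last two = reference).
#' @param n_up,n_down,n_unique planted effect counts, defaults 80/70/8
#'   (88 up in total, 70 down).
#' @param fold planted fold change, default 8.
#' @param grid_size multifunctional-grid size, default 161.
#' @param category_sizes named category sizes, default
#'   \code{\link{panel_category_sizes}}.
#' @param n_biased_diff planted differentially expressed biased-signature
#'   genes (besides the unique genes), default 7.
#' @param list_size size of the metastasis-associated gene list, default 339.
#' @param list_grid_overlap planted overlap of that list with the grid,
#'   default 36.
#' @param outlier name of the outlier case library, default \code{"Met2"}.
#' @param library_sd,outlier_sd log-scale jitter sd, defaults 0.08 and 0.35.
#' @param min_count expression threshold used for the ledger's expressed-set
#'   recounts, default 2.
#' @param qpcr_noise_sd Ct noise for the validation tables, default 0.2.
#' @return object of class \code{sage_scenario}: list with
#'   \code{gene_counts} (named list of named integer vectors),
#'   \code{depths}, \code{assignment}, \code{categories} (with grid),
#'   \code{metastasis_list}, \code{qpcr}, \code{params} and \code{ledger}
#'   (planted up/down/unique sets, biased signature with expected status,
#'   grid, realized expressed/common sets at \code{min_count}, outlier id,
#'   seeds).
#' @export
generate_scenario <- function(seed, n_genes = 5400, depths = panel_depths,
                              n_up = 80, n_down = 70, n_unique = 8,
                              fold = 8, grid_size = 161L,
                              category_sizes = panel_category_sizes,
                              n_biased_diff = 7L, list_size = 339L,
                              list_grid_overlap = 36L, outlier = "Met2",
                              library_sd = 0.08, outlier_sd = 0.35,
                              min_count = 2, qpcr_noise_sd = 0.2) {
  stopifnot(length(depths) == 7, !is.null(names(depths)))
  case_ids <- names(depths)[1:5]
  ref_ids <- names(depths)[6:7]
  stopifnot(outlier %in% case_ids)
  set.seed(as.integer(seed))
  sub <- sample.int(.Machine$integer.max - 1L, 30L)

  base <- generate_transcriptome(n_genes, seed = sub[1L])
  # depth-aware eligibility: a planted downregulated gene must keep an
  # expected count of ~15 in the shallowest library after division by fold,
  # and an upregulated/unique gene needs a detectable baseline (~12)
  min_depth <- min(depths)
  ord <- names(base)[order(base, decreasing = TRUE)]
  eligible_down <- names(base)[base * min_depth >= 15 * fold]
  if (length(eligible_down) < 2L * n_down) {
    eligible_down <- head(ord, 2L * n_down)
  }
  eligible_up <- setdiff(names(base)[base * min_depth >= 12], eligible_down)
  if (length(eligible_up) < 2L * (n_up + n_unique)) {
    eligible_up <- setdiff(head(ord, length(eligible_down) +
                                  2L * (n_up + n_unique)), eligible_down)
  }
  planted <- plant_effects(base, n_up = n_up, n_down = n_down,
                           n_unique = n_unique, fold = fold, seed = sub[2L],
                           eligible_up = eligible_up,
                           eligible_down = eligible_down)

  jitter_abund <- function(abund, sd, s) {
    set.seed(s)
    x <- abund * exp(rnorm(length(abund), 0, sd))
    x[abund == 0] <- 0
    x / sum(x)
  }
  gene_counts <- list()
  for (i in seq_along(case_ids)) {
    id <- case_ids[i]
    sd_i <- if (id == outlier) outlier_sd else library_sd
    ab <- jitter_abund(planted$case, sd_i, sub[2L + i])
    gene_counts[[id]] <- simulate_library(ab, depths[[id]],
                                          seed = sub[9L + i],
                                          library_id = id)
  }
  for (i in seq_along(ref_ids)) {
    id <- ref_ids[i]
    ab <- jitter_abund(planted$reference, library_sd, sub[7L + i])
    gene_counts[[id]] <- simulate_library(ab, depths[[id]],
                                          seed = sub[15L + i],
                                          library_id = id)
  }

  assignment <- make_tag_assignment(names(base))

  biased_diff <- c(head(planted$ledger$up, ceiling(n_biased_diff / 2)),
                   head(planted$ledger$down, floor(n_biased_diff / 2)))
  biased <- data.frame(
    gene_id = c(biased_diff, planted$ledger$unique),
    status = c(ifelse(biased_diff %in% planted$ledger$up,
                      "up_differential", "down_differential"),
               rep("unique_met", length(planted$ledger$unique))),
    stringsAsFactors = FALSE)
  planted_all <- c(planted$ledger$up, planted$ledger$down,
                   planted$ledger$unique)
  cat_gen <- generate_categories(names(base), sizes = category_sizes,
                                 target_grid_size = grid_size,
                                 seed = sub[18L],
                                 force_in_grid = biased$gene_id,
                                 exclude = planted_all)

  set.seed(sub[19L])
  extra_grid <- sample(setdiff(cat_gen$grid, biased$gene_id),
                       list_grid_overlap)
  off_grid <- sample(setdiff(names(base), cat_gen$grid),
                     list_size - list_grid_overlap)
  metastasis_list <- sample(c(extra_grid, off_grid))

  ratios <- matrix(rep(ifelse(biased$status == "down_differential",
                              1 / fold, fold), length(case_ids)),
                   ncol = length(case_ids),
                   dimnames = list(biased$gene_id, case_ids))
  qpcr <- generate_qpcr(ratios, noise_sd = qpcr_noise_sd, seed = sub[20L])

  expressed <- lapply(gene_counts, function(x)
    sort(names(x)[x >= min_count]))
  structure(list(
    gene_counts = gene_counts,
    depths = depths,
    case_ids = case_ids,
    ref_ids = ref_ids,
    assignment = assignment,
    categories = cat_gen$categories,
    category_table = cat_gen$table,
    metastasis_list = metastasis_list,
    qpcr = qpcr,
    params = list(seed = as.integer(seed), n_genes = n_genes, fold = fold,
                  min_count = min_count, outlier = outlier,
                  library_sd = library_sd, outlier_sd = outlier_sd),
    ledger = list(up = sort(c(planted$ledger$up, planted$ledger$unique)),
                  up_fold = planted$ledger$up,
                  down = planted$ledger$down,
                  unique = planted$ledger$unique,
                  biased_signature = biased[order(biased$gene_id), ],
                  grid = cat_gen$grid,
                  list_grid_overlap = list_grid_overlap,
                  expressed = expressed,
                  common_case = sort(Reduce(intersect,
                                            expressed[case_ids])),
                  common_reference = sort(Reduce(intersect,
                                                 expressed[ref_ids])),
                  outlier = outlier,
                  qpcr = qpcr$ledger,
                  sub_seeds = sub)),
    class = "sage_scenario")
}

#' @export
print.sage_scenario <- function(x, ...) {
  cat("synthetic SAGE scenario (seed ", x$params$seed, "): ",
      x$params$n_genes, " genes; libraries ",
      paste(sprintf("%s=%d", names(x$depths), x$depths), collapse = ", "),
      "\n  planted: ", length(x$ledger$up), " up (",
      length(x$ledger$unique), " unique), ", length(x$ledger$down),
      " down, fold ", x$params$fold, "; grid ", length(x$ledger$grid),
      "; outlier ", x$ledger$outlier, "\n", sep = "")
  invisible(x)
}

#' Write a scenario's pipeline inputs to a directory
#'
#' Emits, per library, a tag-count TSV (tag-level via the 1:1 assignment),
#' plus \code{tag_map.tsv}, \code{categories.tsv},
#' \code{metastasis_genes.txt}, \code{qpcr_ct.tsv},
#' \code{qpcr_dilutions.tsv}, \code{qpcr_efficiencies.tsv} and
#' \code{ledger.json}.
#'
#' @param scenario a \code{sage_scenario}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "sage_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tag_of <- setNames(scenario$assignment$table$tag,
                     scenario$assignment$table$gene_id)
  for (id in names(scenario$gene_counts)) {
    counts <- scenario$gene_counts[[id]]
    lib <- tag_library(setNames(as.numeric(counts),
                                unname(tag_of[names(counts)])),
                       library_id = id)
    write_tag_counts(lib, file.path(dir, paste0(id, ".tsv")))
  }
  write_tag_assignment(scenario$assignment, file.path(dir, "tag_map.tsv"))
  write.table(scenario$category_table, file.path(dir, "categories.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("gene_id", "category"))
  writeLines(scenario$metastasis_list,
             file.path(dir, "metastasis_genes.txt"))
  write.table(scenario$qpcr$ct_table, file.path(dir, "qpcr_ct.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(scenario$qpcr$dilution_table,
              file.path(dir, "qpcr_dilutions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  eff <- scenario$qpcr$ledger$efficiencies
  write.table(data.frame(gene_id = names(eff), efficiency = unname(eff)),
              file.path(dir, "qpcr_efficiencies.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ledger <- scenario$ledger
  ledger$qpcr$ratios <- NULL  # matrix; sets and scalars suffice downstream
  jsonlite::write_json(ledger, file.path(dir, "ledger.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
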