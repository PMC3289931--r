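# End-to-end orchestration: tags -> normalize -> virtual reference -> DE ->
# signatures -> enrichment -> clustering -> qPCR, from a directory of
# standard inputs, with a consolidated machine-readable report.

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  message(sprintf("[sagesig] stage %-12s ...", name), appendLF = FALSE)
  out <- tryCatch(force(expr), error = function(e) {
    message(" FAILED")
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  message(sprintf(" done (%.2fs)", proc.time()[["elapsed"]] - t0))
  out
}

#' Default pipeline configuration
#'
#' Every parameter the underlying study left unstated is surfaced here with
#' its default: expression threshold (\code{min_count = 2}, the cluster-size
#' >= 2 convention), two-sided \code{alpha = 0.05} with no multiplicity
#' correction, normalization \code{target = 1e5} tags, per-library
#' consistency for the consistent-DE rule, reference expressed set from the
#' two reference libraries jointly (\code{nm_expressed = "common"}), average
#' linkage, and 100,000 enrichment iterations.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(case_ids = names(panel_depths)[1:5],
       ref_ids = names(panel_depths)[6:7],
       min_count = 2,
       alpha = 0.05,
       target = 1e5,
       consistency = "per_library",
       nm_expressed = "common",
       iterations = 1e5,
       seed = 1L,
       linkage = "average",
       calibrator_id = "NMpool",
       qpcr_ref_gene = "REF18S")
}

#' Run the full comparative SAGE pipeline
#'
#' Expects in \code{input_dir}: one \code{<id>.tsv} tag-count table per
#' library, \code{tag_map.tsv}, \code{categories.tsv},
#' \code{metastasis_genes.txt}, and optionally \code{qpcr_ct.tsv} +
#' \code{qpcr_dilutions.tsv} (the layout written by
#' \code{\link{write_scenario}}).  Stages run in dependency order; a failure
#' aborts with a stage-named error.  Identical inputs, configuration and seed
#' give a byte-identical report body (no timestamps are embedded).
#'
#' @param input_dir input directory.
#' @param out_dir optional output directory for the JSON report, text
#'   summary and intermediate tables.
#' @param config named list overriding entries of
#'   \code{\link{default_config}}.
#' @return object of class \code{sage_run_report}: list with \code{counts}
#'   (all signature cardinalities), \code{percentages} (each with its
#'   numerator and denominator), \code{signature_report},
#'   \code{consistent_de}, \code{enrichment} (per comparison and subset),
#'   \code{newick}, \code{farthest_pair}, \code{cluster_bias}, \code{qpcr},
#'   \code{config}.
#' @export
run_pipeline <- function(input_dir, out_dir = NULL, config = list()) {
  cfg <- utils::modifyList(default_config(), config)
  if (!cfg$nm_expressed %in% c("common", "virtual")) {
    stop("invalid config: nm_expressed must be 'common' or 'virtual'",
         call. = FALSE)
  }
  if (cfg$alpha < 0 || cfg$alpha > 1) {
    stop("invalid config: alpha outside [0, 1]", call. = FALSE)
  }
  ids <- c(cfg$case_ids, cfg$ref_ids)
  paths <- file.path(input_dir, paste0(ids, ".tsv"))
  missing <- paths[!file.exists(paths)]
  for (f in c("tag_map.tsv", "categories.tsv", "metastasis_genes.txt")) {
    if (!file.exists(file.path(input_dir, f))) {
      missing <- c(missing, file.path(input_dir, f))
    }
  }
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  mapping <- .stage("tagmap", read_tag_map(file.path(input_dir,
                                                     "tag_map.tsv")))
  genes <- .stage("tags", {
    libs <- lapply(seq_along(ids), function(i)
      read_tag_counts(paths[i], library_id = ids[i]))
    setNames(lapply(libs, aggregate_to_genes, mapping = mapping), ids)
  })
  normed <- .stage("normalize", setNames(lapply(genes, normalize_library,
                                                target = cfg$target), ids))
  virtual <- .stage("virtual",
                    make_virtual_library(normed[[cfg$ref_ids[1L]]],
                                         normed[[cfg$ref_ids[2L]]]))
  de <- .stage("de", consistent_de(genes[cfg$case_ids], virtual,
                                   alpha = cfg$alpha,
                                   min_count = cfg$min_count,
                                   consistency = cfg$consistency))
  categories <- .stage("categories",
                       read_categories(file.path(input_dir,
                                                 "categories.tsv")))
  grid <- build_grid(categories)
  met_list <- read_gene_list(file.path(input_dir, "metastasis_genes.txt"))

  report <- .stage("signatures", {
    common_met <- common_genes(genes[cfg$case_ids],
                               min_count = cfg$min_count)
    nm_expr <- if (cfg$nm_expressed == "common") {
      common_genes(genes[cfg$ref_ids], min_count = cfg$min_count)
    } else {
      expressed_genes(virtual, min_count = cfg$min_count)
    }
    tab <- build_expression_table(normed[cfg$case_ids])
    build_signature_report(common_met, nm_expr, grid, de,
                           mean_expression = colMeans(tab))
  })
  annotation <- annotate_subset(report, met_list, "metastasis_associated")

  ref_case <- cfg$case_ids[1L]
  enr <- .stage("enrichment", {
    universe <- expressed_genes(genes[[ref_case]],
                                min_count = cfg$min_count)
    subsets <- list(
      metastasis_associated = intersect(met_list, universe),
      multifunctional = intersect(grid, universe))
    out <- list()
    k <- 0L
    for (other in setdiff(cfg$case_ids, ref_case)) {
      pw <- pairwise_de(genes[[ref_case]], genes[[other]],
                        alpha = cfg$alpha, min_count = cfg$min_count)
      de_list <- pw$gene_id[pw$significant]
      for (nm in names(subsets)) {
        k <- k + 1L
        key <- paste(ref_case, "vs", other, nm, sep = "_")
        if (length(de_list) == 0L || length(de_list) >= length(universe)) {
          # degenerate baseline: the binomial test is undefined
          out[[key]] <- structure(list(
            universe_size = length(universe),
            subset_size = length(subsets[[nm]]),
            de_list_size = length(de_list),
            observed_hits = length(intersect(subsets[[nm]], de_list)),
            observed_ratio = NA_real_,
            simulated_baseline_ratio = NA_real_,
            analytic_expectation = length(de_list) / length(universe),
            iterations = 0L, seed = cfg$seed + k,
            p_binomial = NA_real_, alternative = "greater"),
            class = "enrichment_result")
        } else {
          out[[key]] <- run_enrichment(universe, subsets[[nm]], de_list,
                                       iterations = cfg$iterations,
                                       seed = cfg$seed + k)
        }
      }
      bias <- cluster_size_bias(
        setNames(normed[[ref_case]]$counts, names(normed[[ref_case]]$counts)),
        setNames(pw$significant, pw$gene_id))
      attr(out, "bias") <- rbind(attr(out, "bias"),
                                 data.frame(comparison = paste(ref_case,
                                                               "vs", other),
                                            mean_de = bias$mean_de,
                                            mean_non_de = bias$mean_non_de,
                                            n_de = bias$n_de,
                                            n_non_de = bias$n_non_de))
    }
    out
  })
  cluster_bias <- attr(enr, "bias")
  attr(enr, "bias") <- NULL

  dendro <- .stage("clustering", {
    tab <- build_expression_table(normed[ids])
    hierarchical_cluster(correlation_distance(tab,
                                              min_count = cfg$min_count),
                         linkage = cfg$linkage)
  })

  qpcr <- NULL
  ct_path <- file.path(input_dir, "qpcr_ct.tsv")
  if (file.exists(ct_path)) {
    qpcr <- .stage("qpcr", {
      ct <- read_ct_table(ct_path)
      dil <- read_dilution_table(file.path(input_dir, "qpcr_dilutions.tsv"))
      curves <- lapply(split(dil, dil$gene_id), function(d)
        fit_standard_curve(d$log10_dilution, d$ct, gene_id = d$gene_id[1L]))
      eff <- vapply(curves, `[[`, numeric(1), "efficiency")
      list(curves = curves,
           ratios = pfaffl_table(ct, eff,
                                 calibrator_id = cfg$calibrator_id,
                                 ref_gene = cfg$qpcr_ref_gene))
    })
  }

  pct <- function(num, den) {
    list(numerator = num, denominator = den,
         percent = format_percent(num, den))
  }
  counts <- list(
    common_met = length(report$common_met),
    nm_expressed = length(report$nm_expressed),
    grid = length(report$grid),
    consistent_up = length(de$up_genes),
    consistent_down = length(de$down_genes),
    consistent_total = length(de$up_genes) + length(de$down_genes),
    unique_met_expressed = length(de$unique_genes),
    met_signature = length(report$met_signature),
    nm_signature = length(report$nm_signature),
    combined = length(report$combined),
    unique_met = length(report$unique_met),
    unique_nm = length(report$unique_nm),
    shared = length(report$shared),
    biased = nrow(report$biased_signature),
    biased_up = sum(report$biased_signature$status == "up_differential"),
    biased_down = sum(report$biased_signature$status == "down_differential"),
    biased_unique = sum(report$biased_signature$status == "unique_met"))
  out <- structure(list(
    counts = counts,
    percentages = list(
      de_of_common = pct(counts$consistent_total, counts$common_met),
      biased_of_met_signature = pct(counts$biased, counts$met_signature)),
    signature_report = report,
    annotation = annotation,
    consistent_de = de,
    enrichment = enr,
    newick = dendro$newick,
    farthest_pair = farthest_pair(dendro),
    cluster_bias = cluster_bias,
    qpcr = qpcr,
    config = cfg),
    class = "sage_run_report")
  if (!is.null(out_dir)) write_run_report(out, out_dir)
  out
}

#' @export
print.sage_run_report <- function(x, ...) {
  c_ <- x$counts
  p_ <- x$percentages
  cat("comparative SAGE run report\n",
      "  common genes (cases):        ", c_$common_met, "\n",
      "  expressed (reference):       ", c_$nm_expressed, "\n",
      "  consistent DE:               ", c_$consistent_total, " (",
      c_$consistent_up, " up / ", c_$consistent_down, " down) = ",
      p_$de_of_common$percent, "% of common\n",
      "  multifunctional grid:        ", c_$grid, "\n",
      "  case signature:              ", c_$met_signature, "\n",
      "  reference signature:         ", c_$nm_signature, "\n",
      "  combined:                    ", c_$combined, " (",
      c_$unique_met, " unique-case / ", c_$unique_nm,
      " unique-reference / ", c_$shared, " shared)\n",
      "  biased signature:            ", c_$biased, " (",
      c_$biased_up, " up / ", c_$biased_down, " down / ",
      c_$biased_unique, " unique) = ",
      p_$biased_of_met_signature$percent, "% of case signature\n",
      "  farthest pair:               ",
      paste(x$farthest_pair, collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' Write a run report to disk
#'
#' Writes \code{report.json} (machine-readable; no timestamps, so reruns are
#' byte-identical), \code{report.txt} (the printed summary),
#' \code{tree.newick}, and the per-set gene lists.
#'
#' @param report a \code{sage_run_report}.
#' @param out_dir output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  stopifnot(inherits(report, "sage_run_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sr <- report$signature_report
  json <- list(
    counts = report$counts,
    percentages = report$percentages,
    gene_sets = list(met_signature = sr$met_signature,
                     nm_signature = sr$nm_signature,
                     unique_met = sr$unique_met,
                     unique_nm = sr$unique_nm,
                     shared = sr$shared,
                     biased_signature = sr$biased_signature,
                     consistent_up = report$consistent_de$up_genes,
                     consistent_down = report$consistent_de$down_genes),
    annotation = report$annotation,
    enrichment = lapply(report$enrichment, unclass),
    cluster_bias = report$cluster_bias,
    newick = report$newick,
    farthest_pair = report$farthest_pair,
    qpcr_ratios = if (!is.null(report$qpcr)) report$qpcr$ratios,
    config = report$config,
    package_version = as.character(utils::packageVersion("sagesig")))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "report.txt"))
  writeLines(report$newick, file.path(out_dir, "tree.newick"))
  invisible(out_dir)
}

#' Minimal command-line entry point
#'
#' Verbs: \code{synth --seed S --out DIR} (write a study-shaped synthetic
#' scenario), \code{run --in DIR --out DIR [--seed S] [--iterations N]}
#' (run the pipeline), \code{tags --fasta FILE --out FILE} (extract and count
#' tags from concatemer reads).  Installed as
#' \code{system.file("scripts", "sagesig", package = "sagesig")}.
#'
#' @param argv character vector of arguments (default: command line).
#' @return exit status, invisibly (0 on success).
#' @export
sagesig_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    message("usage: sagesig <synth|run|tags> [--seed S] [--in DIR] ",
            "[--out PATH] [--fasta FILE] [--iterations N]")
    invisible(1L)
  }
  if (length(argv) < 1L) return(usage())
  verb <- argv[1L]
  opts <- list()
  args <- argv[-1L]
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--") || i == length(args)) return(usage())
    opts[[substring(args[i], 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  seed <- as.integer(if (is.null(opts$seed)) 1L else opts$seed)
  if (verb == "synth") {
    if (is.null(opts$out)) return(usage())
    scn <- generate_scenario(seed = seed)
    write_scenario(scn, opts$out)
    message("scenario written to ", opts$out)
  } else if (verb == "run") {
    if (is.null(opts$`in`) || is.null(opts$out)) return(usage())
    cfg <- list(seed = seed)
    if (!is.null(opts$iterations)) {
      cfg$iterations <- as.numeric(opts$iterations)
    }
    rep <- run_pipeline(opts$`in`, opts$out, config = cfg)
    print(rep)
  } else if (verb == "tags") {
    if (is.null(opts$fasta) || is.null(opts$out)) return(usage())
    lib <- count_tags_fasta(opts$fasta)
    write_tag_counts(lib, opts$out)
    message("tag table written to ", opts$out)
  } else {
    return(usage())
  }
  invisible(0L)
}
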