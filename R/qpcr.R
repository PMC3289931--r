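# Standard-curve efficiency estimation and Pfaffl relative quantification.
#
# The amplification efficiency E (fold amplification per cycle, 2 = perfect
# doubling) is estimated from a dilution series: Ct regressed on
# log10(dilution) has slope -1/log10(E), so E = 10^(-1/slope).  Relative
# expression of a target gene in a sample versus the calibrator, corrected by
# a reference gene, is
#
#   ratio = E_target^dCt_target / E_ref^dCt_ref,   dCt = Ct(calibrator) - Ct(sample).
#
# The dCt sign convention (calibrator minus sample) matters: flipping it
# inverts every ratio.  With E = 2 for both genes the formula reduces to the
# familiar 2^(-ddCt) method.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(dilution); requires at least three
#' distinct dilution points.
#'
#' @param log10_dilution numeric vector of log10 dilution factors (0 for
#'   undiluted, -1 for 1:10, ...), or a data.frame with columns
#'   \code{log10_dilution} and \code{ct}.
#' @param ct Ct values, parallel to \code{log10_dilution}.
#' @param gene_id gene identifier, default \code{"gene"}.
#' @return object of class \code{standard_curve}: list with \code{gene_id},
#'   \code{slope}, \code{intercept}, \code{r_squared}, \code{efficiency}
#'   (\code{10^(-1/slope)}), \code{n_points}.
#' @examples
#' # perfect doubling: slope -1/log10(2)
#' d <- 0:-3
#' fit_standard_curve(d, 20 - d / log10(2))$efficiency  # 2
#' @export
fit_standard_curve <- function(log10_dilution, ct = NULL, gene_id = "gene") {
  if (is.data.frame(log10_dilution)) {
    ct <- log10_dilution$ct
    log10_dilution <- log10_dilution$log10_dilution
  }
  stopifnot(length(log10_dilution) == length(ct),
            all(is.finite(log10_dilution)), all(is.finite(ct)))
  if (length(unique(log10_dilution)) < 3L) {
    stop("need at least 3 distinct dilution points", call. = FALSE)
  }
  fit <- lm(ct ~ log10_dilution)
  slope <- unname(coef(fit)[2L])
  if (!is.finite(slope) || slope == 0) {
    stop("degenerate standard curve (zero slope)", call. = FALSE)
  }
  if (slope > 0) {
    warning("positive standard-curve slope; check dilution orientation",
            call. = FALSE)
  }
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ct - mean(ct))^2)
  structure(list(gene_id = gene_id,
                 slope = slope,
                 intercept = unname(coef(fit)[1L]),
                 r_squared = if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot,
                 efficiency = 10^(-1 / slope),
                 n_points = length(ct)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("standard curve for ", x$gene_id, ": slope ", signif(x$slope, 5),
      ", E = ", signif(x$efficiency, 5), ", R^2 = ",
      signif(x$r_squared, 5), " (", x$n_points, " points)\n", sep = "")
  invisible(x)
}

#' Pfaffl efficiency-corrected relative expression ratio
#'
#' @param e_target,e_ref amplification efficiencies of the target and
#'   reference gene, each in (1, 2.2].
#' @param ct_target_cal,ct_target_sample target-gene Ct in the calibrator and
#'   the sample.
#' @param ct_ref_cal,ct_ref_sample reference-gene Ct in the calibrator and
#'   the sample.
#' @param gene_id,sample_id,calibrator_id identifiers carried into the
#'   result.
#' @return object of class \code{pfaffl_result}: list with the identifiers,
#'   \code{delta_ct_target}, \code{delta_ct_ref} (calibrator minus sample)
#'   and \code{ratio}.
#' @examples
#' pfaffl_ratio(2, 23, 20, 2, 18, 17)$ratio  # 2^3 / 2^1 = 4
#' @export
pfaffl_ratio <- function(e_target, ct_target_cal, ct_target_sample,
                         e_ref, ct_ref_cal, ct_ref_sample,
                         gene_id = "gene", sample_id = "sample",
                         calibrator_id = "calibrator") {
  ct <- c(ct_target_cal, ct_target_sample, ct_ref_cal, ct_ref_sample)
  if (!all(is.finite(ct)) || any(ct <= 0)) {
    stop("Ct values must be finite and positive", call. = FALSE)
  }
  for (e in c(e_target, e_ref)) {
    if (!is.finite(e) || e <= 1 || e > 2.2) {
      stop("efficiency out of range (1, 2.2]: ", e, call. = FALSE)
    }
  }
  d_t <- ct_target_cal - ct_target_sample
  d_r <- ct_ref_cal - ct_ref_sample
  structure(list(gene_id = gene_id, sample_id = sample_id,
                 calibrator_id = calibrator_id,
                 delta_ct_target = d_t, delta_ct_ref = d_r,
                 ratio = e_target^d_t / e_ref^d_r),
            class = "pfaffl_result")
}

#' @export
print.pfaffl_result <- function(x, ...) {
  cat("Pfaffl ratio ", x$gene_id, " in ", x$sample_id, " vs ",
      x$calibrator_id, ": ", signif(x$ratio, 5), " (dCt target ",
      signif(x$delta_ct_target, 4), ", dCt ref ",
      signif(x$delta_ct_ref, 4), ")\n", sep = "")
  invisible(x)
}

#' Summarize replicate Ct measurements
#'
#' @param ct_table data.frame with columns \code{sample_id}, \code{gene_id},
#'   \code{replicate}, \code{ct}.
#' @param flag_threshold replicates deviating more than this many cycles from
#'   their group mean are flagged, default 0.5.
#' @return data.frame with one row per (sample, gene): \code{sample_id},
#'   \code{gene_id}, \code{mean_ct}, \code{sd_ct} (NA for single replicates,
#'   with a warning), \code{n}, \code{flagged} (any replicate beyond the
#'   threshold).
#' @export
summarize_replicates <- function(ct_table, flag_threshold = 0.5) {
  stopifnot(all(c("sample_id", "gene_id", "ct") %in% names(ct_table)))
  key <- interaction(ct_table$sample_id, ct_table$gene_id, drop = TRUE)
  groups <- split(ct_table, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    m <- mean(g$ct)
    data.frame(sample_id = g$sample_id[1L], gene_id = g$gene_id[1L],
               mean_ct = m,
               sd_ct = if (nrow(g) >= 2L) sd(g$ct) else NA_real_,
               n = nrow(g),
               flagged = any(abs(g$ct - m) > flag_threshold),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (any(out$n < 2L)) {
    warning("single-replicate group(s): mean passed through without sd",
            call. = FALSE)
  }
  out[order(out$sample_id, out$gene_id), , drop = FALSE]
}

#' Read a Ct table
#'
#' TSV with header columns \code{sample_id}, \code{gene_id},
#' \code{replicate}, \code{ct}.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "gene_id", "replicate", "ct") %in% names(df)))
  df
}

#' Read dilution-series tables
#'
#' TSV with header columns \code{gene_id}, \code{log10_dilution}, \code{ct}.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_dilution_table <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "log10_dilution", "ct") %in% names(df)))
  df
}

#' Pfaffl quantification for a full Ct table
#'
#' Averages replicates, then computes the Pfaffl ratio of every target gene
#' in every non-calibrator sample against the calibrator, corrected by the
#' reference gene.
#'
#' @param ct_table data.frame as in \code{\link{read_ct_table}}.
#' @param efficiencies named numeric vector of per-gene efficiencies (must
#'   cover every gene in the table).
#' @param calibrator_id sample id of the calibrator.
#' @param ref_gene reference (housekeeping) gene id.
#' @return data.frame with columns \code{gene_id}, \code{sample_id},
#'   \code{calibrator_id}, \code{delta_ct_target}, \code{delta_ct_ref},
#'   \code{ratio}.
#' @export
pfaffl_table <- function(ct_table, efficiencies, calibrator_id, ref_gene) {
  means <- summarize_replicates(ct_table)
  genes <- setdiff(unique(means$gene_id), ref_gene)
  samples <- setdiff(unique(means$sample_id), calibrator_id)
  if (!all(c(genes, ref_gene) %in% names(efficiencies))) {
    stop("missing efficiencies for some genes", call. = FALSE)
  }
  ct_of <- function(s, g) {
    v <- means$mean_ct[means$sample_id == s & means$gene_id == g]
    if (length(v) != 1L) {
      stop("missing Ct for sample ", s, ", gene ", g, call. = FALSE)
    }
    v
  }
  rows <- lapply(genes, function(g) {
    do.call(rbind, lapply(samples, function(s) {
      r <- pfaffl_ratio(efficiencies[[g]], ct_of(calibrator_id, g),
                        ct_of(s, g), efficiencies[[ref_gene]],
                        ct_of(calibrator_id, ref_gene),
                        ct_of(s, ref_gene),
                        gene_id = g, sample_id = s,
                        calibrator_id = calibrator_id)
      data.frame(gene_id = g, sample_id = s, calibrator_id = calibrator_id,
                 delta_ct_target = r$delta_ct_target,
                 delta_ct_ref = r$delta_ct_ref, ratio = r$ratio,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
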