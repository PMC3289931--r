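# Resampling baseline and exact binomial enrichment test.
#
# To ask whether a gene subset (e.g. the metastasis-associated or
# multifunctional genes expressed in the reference metastasis) is enriched in
# a list of significantly differentially expressed genes, the baseline hit
# ratio is estimated by repeatedly drawing subsets of the same size uniformly
# without replacement from the expressed universe; the observed hit count is
# then compared with that baseline by a one-sample exact binomial test
# (one-sided "greater" by default).  The analytic expectation of the baseline
# is |DE| / |universe| regardless of the draw scheme.

#' Simulate the baseline hit ratio for random gene subsets
#'
#' Each iteration samples \code{subset_size} genes uniformly without
#' replacement from \code{universe} and records the fraction belonging to
#' \code{de_list}.  Fully determined by \code{seed}.
#'
#' @param universe character vector of gene ids.
#' @param subset_size number of genes drawn per iteration.
#' @param de_list character vector, subset of \code{universe}.
#' @param iterations number of Monte-Carlo iterations, default 100000.
#' @param seed integer RNG seed (required: the baseline must be
#'   reproducible).
#' @return list with \code{mean_ratio}, \code{sd_ratio},
#'   \code{analytic_expectation} (\code{length(de_list)/length(universe)}),
#'   \code{iterations}, \code{seed}.
#' @export
simulate_baseline <- function(universe, subset_size, de_list,
                              iterations = 1e5, seed) {
  stopifnot(length(universe) >= 1, subset_size >= 1, iterations >= 1)
  if (subset_size > length(universe)) {
    stop("subset_size exceeds the universe size", call. = FALSE)
  }
  if (!all(de_list %in% universe)) {
    stop("de_list must be a subset of the universe", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n <- length(universe)
  de <- universe %in% de_list
  ratios <- vapply(seq_len(iterations), function(i) {
    sum(de[sample.int(n, subset_size)])
  }, numeric(1)) / subset_size
  list(mean_ratio = mean(ratios),
       sd_ratio = sd(ratios),
       analytic_expectation = sum(de) / n,
       iterations = as.integer(iterations),
       seed = as.integer(seed))
}

#' One-sample exact binomial enrichment test
#'
#' Tail probability of observing at least \code{observed_hits} successes in
#' \code{subset_size} trials under \code{Binomial(subset_size, baseline_p)}
#' (alternative \code{"greater"}), or the two-sided p-value by the
#' point-probability method.
#'
#' @param observed_hits observed number of subset genes in the DE list.
#' @param subset_size subset size (number of trials).
#' @param baseline_p baseline success probability in (0, 1), typically the
#'   simulated mean ratio.
#' @param alternative \code{"greater"} (default) or \code{"two_sided"}.
#' @return the p-value.
#' @export
binomial_enrichment <- function(observed_hits, subset_size, baseline_p,
                                alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  stopifnot(observed_hits >= 0, observed_hits <= subset_size,
            subset_size >= 1)
  if (baseline_p <= 0 || baseline_p >= 1) {
    stop("degenerate baseline probability: ", baseline_p, call. = FALSE)
  }
  if (alternative == "greater") {
    pbinom(observed_hits - 1, subset_size, baseline_p, lower.tail = FALSE)
  } else {
    d <- dbinom(0:subset_size, subset_size, baseline_p)
    # point-probability method with the customary relative fuzz
    sum(d[d <= dbinom(observed_hits, subset_size, baseline_p) *
            (1 + 1e-7)])
  }
}

#' Run the full enrichment analysis for one subset
#'
#' @inheritParams simulate_baseline
#' @param subset character vector of genes, subset of \code{universe}.
#' @param alternative passed to \code{\link{binomial_enrichment}}.
#' @return object of class \code{enrichment_result}: list with
#'   \code{universe_size}, \code{subset_size}, \code{de_list_size},
#'   \code{observed_hits}, \code{observed_ratio},
#'   \code{simulated_baseline_ratio}, \code{analytic_expectation},
#'   \code{iterations}, \code{seed}, \code{p_binomial},
#'   \code{alternative}.
#' @export
run_enrichment <- function(universe, subset, de_list, iterations = 1e5,
                           seed, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (!all(subset %in% universe)) {
    stop("subset must be contained in the universe", call. = FALSE)
  }
  observed <- length(intersect(subset, de_list))
  base <- simulate_baseline(universe, length(subset), de_list,
                            iterations = iterations, seed = seed)
  structure(list(universe_size = length(universe),
                 subset_size = length(subset),
                 de_list_size = length(intersect(de_list, universe)),
                 observed_hits = observed,
                 observed_ratio = observed / length(subset),
                 simulated_baseline_ratio = base$mean_ratio,
                 analytic_expectation = base$analytic_expectation,
                 iterations = base$iterations,
                 seed = base$seed,
                 p_binomial = binomial_enrichment(observed, length(subset),
                                                  base$mean_ratio,
                                                  alternative),
                 alternative = alternative),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment: ", x$observed_hits, "/", x$subset_size,
      " subset genes in DE list (ratio ", signif(x$observed_ratio, 4),
      ") vs baseline ", signif(x$simulated_baseline_ratio, 4),
      " (", x$iterations, " iterations, seed ", x$seed, "); binomial p = ",
      format(x$p_binomial, digits = 4), " [", x$alternative, "]\n",
      sep = "")
  invisible(x)
}
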