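test_that("ztest_counts matches hand computations and is antisymmetric", {
  # equal proportions: z = 0, p = 1
  eq <- ztest_counts(5, 1e5, 5, 1e5)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  # hand-computed: p0 = 5e-5, se = sqrt(p0(1-p0)*2e-5)
  zt <- ztest_counts(10, 1e5, 0, 1e5)
  expect_equal(zt$z, 1e-4 / sqrt(5e-5 * (1 - 5e-5) * 2e-5),
               tolerance = 1e-12)
  expect_equal(zt$z, 3.162, tolerance = 1e-3)
  # swapping libraries negates z, keeps p
  ab <- ztest_counts(17, 9e4, 4, 11e4)
  ba <- ztest_counts(4, 11e4, 17, 9e4)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  # both counts zero: non-testable
  nn <- ztest_counts(0, 100, 0, 100)
  expect_true(is.na(nn$z) && is.na(nn$p))
})

test_that("z^2 equals the Pearson chi-square statistic (oracle equivalence)", {
  set.seed(101)
  n <- 2000
  n_a <- sample(50:20000, n, replace = TRUE)
  n_b <- sample(50:20000, n, replace = TRUE)
  c_a <- rbinom(n, n_a, runif(n, 0, 0.05))
  c_b <- rbinom(n, n_b, runif(n, 0, 0.05))
  keep <- (c_a + c_b) > 0
  zt <- ztest_counts(c_a[keep], n_a[keep], c_b[keep], n_b[keep])
  x2 <- oracle_chisq_2x2(c_a[keep], n_a[keep], c_b[keep], n_b[keep])
  expect_true(all(abs(zt$z^2 - x2) <= 1e-9 * pmax(1, x2)))
})

test_that("z-test is calibrated where the normal approximation holds", {
  # discrete small-count genes make the test conservative; in the counts>=10
  # regime the rejection rate must sit within pooled binomial 99% bounds
  tot <- 0L; sig <- 0L
  for (s in 1:8) {
    ab <- generate_transcriptome(2000, seed = 500 + s)
    a <- simulate_library(ab, 1e5, seed = 600 + s)
    b <- simulate_library(ab, 1e5, seed = 700 + s)
    pw <- pairwise_de(a, b, alpha = 0.05, min_count = 10)
    tot <- tot + nrow(pw); sig <- sig + sum(pw$significant)
  }
  bounds <- qbinom(c(0.005, 0.995), tot, 0.05)
  expect_gte(sig, bounds[1L])
  expect_lte(sig, bounds[2L])
})

test_that("pairwise_de defines the universe from the reference library", {
  f <- fixture_counts()
  res <- pairwise_de(f$a, f$b, min_count = 2)
  expect_setequal(res$gene_id, c("g1", "g2", "g3", "g4"))  # g5 below cutoff
  expect_identical(res$unique_to[res$gene_id == "g4"], "a")  # absent in b
  # identical libraries: nothing significant at any alpha
  same <- pairwise_de(f$a, f$a, alpha = 0.5)
  expect_false(any(same$significant))
  expect_true(all(same$direction == "equal"))
  # alpha 0 switches everything off
  none <- pairwise_de(f$a, f$b, alpha = 0)
  expect_false(any(none$significant))
  # direction consistent with the proportion difference
  expect_true(all((res$proportion_a > res$proportion_b) ==
                    (res$direction == "up_in_a")))
})

test_that("pairwise_de detects planted 8-fold changes with high power", {
  ab <- generate_transcriptome(2000, seed = 31)
  pl <- plant_effects(ab, n_up = 50, n_down = 0, n_unique = 0, fold = 8,
                      seed = 32)
  a <- simulate_library(pl$case, 1e5, seed = 33)
  b <- simulate_library(pl$reference, 1e5, seed = 34)
  res <- pairwise_de(a, b, alpha = 0.05, min_count = 2)
  hit <- res$significant[match(pl$ledger$up, res$gene_id)]
  expect_gte(mean(hit, na.rm = TRUE), 0.9)
})

test_that("consistent_de applies the all-libraries rule with direction", {
  # gene ids: u (up everywhere), d (down everywhere), m (missing in one
  # case library), i (inconsistent direction), q (unique to cases)
  ref <- normalize_library(c(u = 20, d = 160, m = 50, i = 50, f = 300,
                             filler = 420), target = 1e3)
  mk <- function(u, d, m, i, q) c(u = u, d = d, m = m, i = i, q = q,
                                  f = 300)
  cases <- list(L1 = mk(160, 20, 50, 200, 30),
                L2 = mk(160, 20, 50, 200, 30),
                L3 = mk(160, 20, 1, 200, 30),   # m not expressed here
                L4 = mk(160, 20, 50, 200, 30),
                L5 = mk(160, 20, 50, 5, 30))    # i flips here
  # give each case library a realistic total so z-tests have power
  cases <- lapply(cases, function(x) c(x, filler = 1000 - sum(x)))
  de <- consistent_de(cases, ref, alpha = 0.05, min_count = 2)
  expect_true("u" %in% de$up_genes)
  expect_true("d" %in% de$down_genes)
  expect_false("m" %in% c(de$up_genes, de$down_genes))
  expect_false("i" %in% c(de$up_genes, de$down_genes))
  expect_true("q" %in% de$up_genes)        # absent in reference: unique-up
  expect_true("q" %in% de$unique_genes)
  expect_false("f" %in% c(de$up_genes, de$down_genes))  # null gene
  expect_length(intersect(de$up_genes, de$down_genes), 0)
})

test_that("consistent_de recovers planted genes (generator ledger)", {
  ab <- generate_transcriptome(1500, seed = 61)
  pl <- plant_effects(ab, n_up = 20, n_down = 10, n_unique = 4, fold = 8,
                      seed = 62)
  cases <- lapply(1:5, function(i)
    simulate_library(pl$case, 9e4, seed = 70 + i))
  names(cases) <- paste0("M", 1:5)
  refs <- lapply(1:2, function(i)
    simulate_library(pl$reference, 8e4, seed = 80 + i))
  virt <- make_virtual_library(normalize_library(refs[[1]]),
                               normalize_library(refs[[2]]))
  de <- consistent_de(cases, virt)
  expect_true(all(c(pl$ledger$up, pl$ledger$unique) %in% de$up_genes))
  expect_true(all(pl$ledger$down %in% de$down_genes))
  expect_true(all(pl$ledger$unique %in% de$unique_genes))
  # pooled mode recovers the planted genes as well
  dep <- consistent_de(cases, virt, consistency = "pooled")
  expect_true(all(c(pl$ledger$up, pl$ledger$unique) %in% dep$up_genes))
  expect_true(all(pl$ledger$down %in% dep$down_genes))
})

test_that("cluster_size_bias groups means by significance flag", {
  counts <- c(a = 10, b = 10, c = 40, d = 40)
  flags <- c(a = FALSE, b = FALSE, c = TRUE, d = TRUE)
  cb <- cluster_size_bias(counts, flags)
  expect_equal(cb$mean_de, 40)
  expect_equal(cb$mean_non_de, 10)
  # equal counts: both means equal
  cb2 <- cluster_size_bias(c(a = 7, b = 7), c(a = TRUE, b = FALSE))
  expect_equal(cb2$mean_de, cb2$mean_non_de)
  # empty group reported as missing; subset restriction honored
  cb3 <- cluster_size_bias(counts, flags, subset = c("c", "d"))
  expect_true(is.na(cb3$mean_non_de))
  expect_equal(cb3$mean_de, 40)
  expect_equal(cb3$n_de, 2)
})
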