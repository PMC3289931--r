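test_that("generate_transcriptome is seeded, normalized and heavy-tailed", {
  a1 <- generate_transcriptome(4200, sigma = 1.5, seed = 1)
  a2 <- generate_transcriptome(4200, sigma = 1.5, seed = 1)
  expect_identical(a1, a2)
  expect_equal(sum(a1), 1, tolerance = 1e-12)
  expect_true(all(a1 > 0))
  # sigma 0: uniform
  u <- generate_transcriptome(10, sigma = 0, seed = 2)
  expect_true(all(abs(u - 0.1) < 1e-12))
  # heavy tail: top decile carries the majority of the mass.  For
  # LN(0, 1.5), P(X > q90) mass fraction = 1 - Phi(Phi^-1(0.9) - 1.5) ~ 0.59
  top <- sum(sort(a1, decreasing = TRUE)[1:420])
  expect_gt(top, 0.5)
  expect_lt(abs(top - (1 - pnorm(qnorm(0.9) - 1.5))), 0.05)
})

test_that("plant_effects plants folds and zeroes uniquely expressed genes", {
  ab <- generate_transcriptome(800, seed = 3)
  # fold 1: conditions identical apart from the unique zeros
  pl1 <- plant_effects(ab, n_up = 5, n_down = 5, n_unique = 0, fold = 1,
                       seed = 4)
  expect_equal(pl1$case, pl1$reference, tolerance = 1e-12)
  pl <- plant_effects(ab, n_up = 12, n_down = 9, n_unique = 10, fold = 8,
                      seed = 5)
  expect_length(pl$ledger$unique, 10)
  expect_true(all(pl$reference[pl$ledger$unique] == 0))
  expect_true(all(pl$case[pl$ledger$unique] > 0))
  expect_equal(sum(pl$case), 1, tolerance = 1e-12)
  expect_equal(sum(pl$reference), 1, tolerance = 1e-12)
  # planted folds hold on the pre-normalization scale (common factor cancels
  # in ratios of case to reference for up vs a null gene)
  null_gene <- setdiff(names(ab), c(pl$ledger$up, pl$ledger$down,
                                    pl$ledger$unique))[1L]
  rel <- (pl$case / pl$reference) / (pl$case[null_gene] /
                                       pl$reference[null_gene])
  expect_equal(unname(rel[pl$ledger$up]), rep(8, 12), tolerance = 1e-9)
  expect_equal(unname(rel[pl$ledger$down]), rep(1 / 8, 9), tolerance = 1e-9)
})

test_that("simulate_library draws the requested depth with expected counts", {
  ab <- generate_transcriptome(300, seed = 6)
  lib <- simulate_library(ab, 50000, seed = 7)
  expect_equal(sum(lib), 50000)
  expect_identical(lib, simulate_library(ab, 50000, seed = 7))
  # single-gene transcriptome: all tags to that gene
  single <- setNames(1, "only")
  expect_equal(unname(simulate_library(single, 10, seed = 8)["only"]), 10)
  # chi-square goodness of fit against the multinomial expectation
  exp_counts <- ab * 50000
  full <- setNames(numeric(length(ab)), names(ab))
  full[names(lib)] <- lib
  keep <- exp_counts >= 5
  x2 <- sum((full[keep] - exp_counts[keep])^2 / exp_counts[keep])
  expect_lt(x2, qchisq(0.999, sum(keep) - 1))
})

test_that("tag assignment is CATG-free and exercises ambiguity", {
  ta <- make_tag_assignment(sprintf("G%03d", 1:50))
  expect_false(any(grepl("CATG", ta$table$tag)))
  expect_length(ta$map$ambiguous, 0)
  expect_equal(anyDuplicated(ta$table$tag), 0)
  ta2 <- make_tag_assignment(sprintf("G%03d", 1:50),
                             ambiguous_fraction = 0.2, seed = 9)
  expect_equal(length(ta2$map$ambiguous), 10)
})

test_that("generate_categories hits exact sizes and an exact grid", {
  genes <- sprintf("G%04d", 1:1200)
  sizes <- setNames(c(60, 140, 55, 40, 120, 45, 30, 50),
                    metastasis_category_names)
  g <- generate_categories(genes, sizes = sizes, target_grid_size = 70,
                           seed = 10, force_in_grid = genes[1:12])
  expect_length(g$grid, 70)
  expect_true(all(genes[1:12] %in% g$grid))
  expect_equal(vapply(g$categories$categories, length, integer(1)),
               sizes)
  expect_setequal(build_grid(g$categories), g$grid)
  # infeasible targets rejected
  expect_error(generate_categories(genes[1:20], sizes = sizes,
                                   target_grid_size = 10, seed = 1),
               "infeasible")
})

test_that("scenario generation is reproducible and internally consistent", {
  small_sizes <- setNames(c(30, 60, 25, 20, 50, 25, 18, 28),
                          metastasis_category_names)
  args <- list(seed = 9, n_genes = 900,
               depths = c(Met1 = 9000, Met2 = 11000, Met3 = 10000,
                          Met4 = 8000, Met5 = 9000, NM1 = 7700,
                          NM2 = 7800),
               n_up = 10, n_down = 8, n_unique = 3, grid_size = 40,
               category_sizes = small_sizes, list_size = 50,
               list_grid_overlap = 8)
  s1 <- do.call(generate_scenario, args)
  s2 <- do.call(generate_scenario, args)
  expect_identical(s1$gene_counts, s2$gene_counts)
  expect_identical(s1$ledger, s2$ledger)
  # planted structure is coherent
  expect_length(s1$ledger$up, 13)          # 10 fold + 3 unique
  expect_length(s1$ledger$down, 8)
  expect_equal(nrow(s1$ledger$biased_signature), 7 + 3)
  expect_true(all(s1$ledger$biased_signature$gene_id %in% s1$ledger$grid))
  # unique genes absent from both reference libraries
  for (id in s1$ref_ids) {
    expect_false(any(s1$ledger$unique %in% names(s1$gene_counts[[id]])))
  }
  # library depths are honored
  for (id in names(s1$depths)) {
    expect_equal(sum(s1$gene_counts[[id]]), unname(s1$depths[id]))
  }
})

test_that("write_scenario emits a complete, readable input directory", {
  scn <- generate_scenario(seed = 11, n_genes = 600,
                           depths = c(Met1 = 6000, Met2 = 7000,
                                      Met3 = 6500, Met4 = 5500,
                                      Met5 = 6000, NM1 = 5000, NM2 = 5200),
                           n_up = 6, n_down = 5, n_unique = 2,
                           grid_size = 30,
                           category_sizes = setNames(
                             c(20, 40, 18, 14, 35, 16, 12, 20),
                             metastasis_category_names),
                           list_size = 30, list_grid_overlap = 5)
  d <- tempfile()
  write_scenario(scn, d)
  files <- c(paste0(names(scn$depths), ".tsv"), "tag_map.tsv",
             "categories.tsv", "metastasis_genes.txt", "qpcr_ct.tsv",
             "qpcr_dilutions.tsv", "ledger.json")
  expect_true(all(file.exists(file.path(d, files))))
  # tag tables aggregate back to the generated gene counts
  mp <- read_tag_map(file.path(d, "tag_map.tsv"))
  lib <- read_tag_counts(file.path(d, "Met1.tsv"), library_id = "Met1")
  gc <- aggregate_to_genes(lib, mp)
  orig <- scn$gene_counts$Met1
  expect_equal(gc$counts[sort(names(orig))], orig[sort(names(orig))])
  expect_equal(gc$unmapped_total + gc$ambiguous_total, 0)
})
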