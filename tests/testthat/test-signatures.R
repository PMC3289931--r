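test_that("expressed_genes and common_genes apply the count threshold", {
  f <- fixture_counts()
  expect_setequal(expressed_genes(f$a, min_count = 1), names(f$a))
  expect_setequal(expressed_genes(f$a, min_count = 2),
                  c("g1", "g2", "g3", "g4"))
  # intersection is idempotent; disjoint libraries give the empty set
  expect_setequal(common_genes(list(f$a, f$a, f$a)),
                  expressed_genes(f$a))
  expect_length(common_genes(list(c(x = 5), c(y = 5))), 0)
  expect_setequal(common_genes(list(f$a, f$b)), c("g1", "g2", "g3"))
})

test_that("build_grid matches a brute-force membership recount", {
  # trivial cases
  one <- functional_categories(
    c(setNames(list(c("a", "b"), c("b")), metastasis_category_names[1:2]),
      setNames(rep(list(character(0)), 6), metastasis_category_names[3:8])))
  expect_identical(build_grid(one), "b")
  # random categories vs oracle
  set.seed(9)
  genes <- sprintf("g%03d", 1:150)
  sets <- setNames(lapply(1:8, function(i) sample(genes, 40)),
                   metastasis_category_names)
  cats <- functional_categories(sets)
  m <- oracle_membership(cats)
  for (k in 1:4) {
    expect_setequal(build_grid(cats, min_categories = k),
                    names(m)[m >= k])
  }
  # disjoint categories: empty grid; identical categories: grid = the set
  disj <- functional_categories(setNames(
    lapply(0:7, function(i) genes[i * 10 + 1:10]),
    metastasis_category_names))
  expect_length(build_grid(disj), 0)
  same <- functional_categories(setNames(rep(list(genes[1:7]), 8),
                                         metastasis_category_names))
  expect_setequal(build_grid(same), genes[1:7])
})

test_that("functional_categories enforces the configured names", {
  expect_error(functional_categories(list(foo = "g1")), "category names")
  expect_error(functional_categories(
    setNames(rep(list("g"), 7), metastasis_category_names[1:7])),
    "missing")
})

test_that("format_percent rounds half-up at the requested precision", {
  expect_equal(format_percent(158, 1488), 10.6)
  expect_equal(format_percent(15, 38), 39.5)
  expect_equal(format_percent(27, 74, digits = 0), 36)
  # half-up, not banker's rounding
  expect_equal(format_percent(1, 800), 0.1)     # 0.125 -> 0.1
  expect_equal(format_percent(15, 1000), 1.5)
  expect_equal(format_percent(5, 2000, digits = 0), 0)
  expect_equal(format_percent(25, 1000, digits = 0), 3)  # 2.5 -> 3
  expect_true(is.na(format_percent(1, 0)))
})

test_that("build_signature_report computes the nested set algebra", {
  de <- structure(list(up_genes = c("g1", "g7"), down_genes = "g2",
                       unique_genes = "g7"), class = "consistent_de_set")
  common_met <- c("g1", "g2", "g3", "g4", "g7")
  nm_expr <- c("g2", "g3", "g5", "g6")
  grid <- c("g1", "g2", "g3", "g5", "g7", "g9")
  rep <- build_signature_report(common_met, nm_expr, grid, de,
                                mean_expression = c(g1 = 10, g2 = 20,
                                                    g3 = 30, g5 = 40,
                                                    g7 = 50))
  expect_setequal(rep$met_signature, c("g1", "g2", "g3", "g7"))
  expect_setequal(rep$nm_signature, c("g2", "g3", "g5"))
  expect_setequal(rep$combined, c("g1", "g2", "g3", "g5", "g7"))
  expect_setequal(rep$unique_met, c("g1", "g7"))
  expect_setequal(rep$unique_nm, "g5")
  expect_setequal(rep$shared, c("g2", "g3"))
  expect_true(rep$inclusion_exclusion_ok)
  # biased signature with status labels
  expect_equal(nrow(rep$biased_signature), 3)
  st <- setNames(rep$biased_signature$status, rep$biased_signature$gene_id)
  expect_identical(unname(st["g1"]), "up_differential")
  expect_identical(unname(st["g2"]), "down_differential")
  expect_identical(unname(st["g7"]), "unique_met")
  # percentage: 3 of 4 signature genes
  expect_equal(rep$percentages$biased_of_met_signature, 75)
  # subset means from the supplied expression vector
  expect_equal(rep$mean_expression$unique_met, 30)  # mean(10, 50)
  # invariants
  expect_true(all(rep$biased_signature$gene_id %in% rep$met_signature))
  expect_length(intersect(rep$unique_met, rep$nm_signature), 0)
})

test_that("degenerate grids give empty signatures with a warning", {
  de <- structure(list(up_genes = "a", down_genes = character(0),
                       unique_genes = character(0)),
                  class = "consistent_de_set")
  expect_warning(rep <- build_signature_report(c("a", "b"), "b",
                                               character(0), de),
                 "empty")
  expect_length(rep$met_signature, 0)
  expect_equal(nrow(rep$biased_signature), 0)
  # grid disjoint from the common set: empty signature, no biased genes
  rep2 <- build_signature_report(c("a", "b"), "b", "zz", de)
  expect_length(rep2$met_signature, 0)
})

test_that("annotate_subset reports overlaps with every set", {
  de <- structure(list(up_genes = "g1", down_genes = character(0),
                       unique_genes = character(0)),
                  class = "consistent_de_set")
  rep <- build_signature_report(c("g1", "g2"), "g2", c("g1", "g2"), de)
  ann <- annotate_subset(rep, c("g1", "g2"), "all")
  expect_equal(ann$overlap[ann$set == "met_signature"], 2L)
  empty <- annotate_subset(rep, character(0), "none")
  expect_true(all(empty$overlap == 0L))
})

test_that("scenario ledger predicts expressed and grid sets exactly", {
  scn <- generate_scenario(seed = 3, n_genes = 900,
                           depths = c(Met1 = 9000, Met2 = 11000,
                                      Met3 = 10000, Met4 = 8000,
                                      Met5 = 9000, NM1 = 7700, NM2 = 7800),
                           n_up = 10, n_down = 8, n_unique = 3,
                           grid_size = 40,
                           category_sizes = setNames(
                             c(30, 60, 25, 20, 50, 25, 18, 28),
                             metastasis_category_names),
                           list_size = 50, list_grid_overlap = 8)
  for (id in names(scn$gene_counts)) {
    expect_setequal(expressed_genes(scn$gene_counts[[id]]),
                    scn$ledger$expressed[[id]])
  }
  expect_setequal(common_genes(scn$gene_counts[scn$case_ids]),
                  scn$ledger$common_case)
  expect_setequal(build_grid(scn$categories), scn$ledger$grid)
  expect_setequal(oracle_membership(scn$categories)[
    oracle_membership(scn$categories) >= 2] |> names(),
    scn$ledger$grid)
  expect_equal(length(intersect(scn$metastasis_list, scn$ledger$grid)),
               scn$ledger$list_grid_overlap)
})
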