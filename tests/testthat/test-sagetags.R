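test_that("extract_ditags finds in-bounds segments between anchoring sites", {
  expect_identical(extract_ditags("CATGAAAAAAAAAATTTTTTTTTTCATG"),
                   "AAAAAAAAAATTTTTTTTTT")
  # zero-length and out-of-bounds segments rejected
  expect_identical(extract_ditags("CATGCATG"), character(0))
  expect_identical(extract_ditags(strrep("A", 100)), character(0))
  # leading/trailing sequence outside the anchored region is never a ditag
  s <- paste0(strrep("T", 25), "CATG", strrep("A", 22), "CATG",
              strrep("G", 30))
  expect_identical(extract_ditags(s), strrep("A", 22))
  # multiple ditags keep order of appearance; bounds are inclusive
  s2 <- paste0("CATG", strrep("A", 20), "CATG", strrep("C", 26), "CATG",
               strrep("G", 19), "CATG", strrep("T", 27), "CATG")
  expect_identical(extract_ditags(s2), c(strrep("A", 20), strrep("C", 26)))
  # no returned segment ever contains the anchor
  expect_false(any(grepl("CATG", extract_ditags(s2), fixed = TRUE)))
  # read shorter than one site: empty, not an error
  expect_identical(extract_ditags("CAT"), character(0))
  expect_error(extract_ditags("CATX"), "outside")
})

test_that("split_ditag returns forward tag and reverse complement tag", {
  expect_identical(split_ditag("AAAAAAAAAATTTTTTTTTT"),
                   c("AAAAAAAAAA", "AAAAAAAAAA"))
  # hand-computed reverse complement of the last 10 bases
  expect_identical(split_ditag("ACGTACGTACGTACGTACGTAC"),
                   c("ACGTACGTAC", "GTACGTACGT"))
  # short ditags in [tag_len, 2*tag_len) give two overlapping tags
  expect_identical(split_ditag("ACGTACGTACGTAC", tag_len = 10L),
                   c("ACGTACGTAC", "GTACGTACGT"))
  expect_error(split_ditag("ACGT", tag_len = 10L), "shorter")
})

test_that("count_tags handles deduplication, blacklist and N tags", {
  dt <- rep("AAAAAAAAAATTTTTTTTTT", 2)  # both tags are A10
  lib_on <- count_tags(dt, dedupe = TRUE)
  lib_off <- count_tags(dt, dedupe = FALSE)
  expect_equal(unname(lib_on$counts["AAAAAAAAAA"]), 2)   # one ditag, 2 tags
  expect_equal(unname(lib_off$counts["AAAAAAAAAA"]), 4)
  expect_equal(lib_on$stats$n_ditags_used, 1L)
  # blacklist removes the tag from counts but records it
  lib_bl <- count_tags("ACGTACGTACCCCCCCCCCC", dedupe = FALSE,
                       linker_blacklist = "ACGTACGTAC")
  expect_false("ACGTACGTAC" %in% names(lib_bl$counts))
  expect_equal(lib_bl$stats$n_blacklisted, 1L)
  # N-containing tags are discarded with a warning and counted
  expect_warning(lib_n <- count_tags("NCGTACGTACCCCCCCCCCC", dedupe = FALSE),
                 "N")
  expect_equal(lib_n$stats$n_tags_with_N, 1L)
  expect_equal(lib_n$total_tags, 1L)
  # empty input gives an empty library, not an error
  empty <- count_tags(character(0))
  expect_equal(empty$total_tags, 0L)
})

test_that("aggregate_to_genes sums per gene and conserves totals", {
  lib <- tag_library(c(AAAAAAAAAA = 3, CCCCCCCCCC = 4, GGGGGGGGGG = 2,
                       TTTTTTTTTT = 5, AAAAACCCCC = 7))
  mp <- tag_map(c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG", "GGGGGGGGGG"),
                c("G1", "G1", "G2", "G3"))  # GGGGGGGGGG ambiguous
  res <- aggregate_to_genes(lib, mp)
  expect_equal(unname(res$counts["G1"]), 7)          # 3 + 4
  expect_equal(res$ambiguous_total, 2)
  expect_equal(res$unmapped_total, 12)               # TTTT... + AAAAACCCCC
  expect_equal(sum(res$counts) + res$unmapped_total + res$ambiguous_total,
               lib$total_tags)
  # keep_first assigns the ambiguous tag to its first-listed gene
  res2 <- aggregate_to_genes(lib, mp, ambiguous_policy = "keep_first")
  expect_equal(unname(res2$counts["G2"]), 2)
  expect_equal(res2$ambiguous_total, 0)
  expect_equal(sum(res2$counts) + res2$unmapped_total, lib$total_tags)
})

test_that("synthetic concatemer round-trip recovers the planted library", {
  ab <- generate_transcriptome(60, seed = 5)
  assign <- make_tag_assignment(names(ab))
  lib <- simulate_library(ab, 800, seed = 6, library_id = "RT",
                          assignment = assign)
  # no duplicates, dedupe off: exact multiset recovery through FASTA
  em <- emit_concatemers(lib, seed = 7, duplicate_rate = 0)
  fa <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(em$reads), "\n", em$reads), fa)
  rec <- count_tags_fasta(fa, dedupe = FALSE, library_id = "RT")
  expect_equal(rec$counts[order(names(rec$counts))],
               em$ledger$tag_counts_emitted[order(names(em$ledger$tag_counts_emitted))])
  # extraction recovers the exact planted ditag multiset
  reads <- read_concatemer_fasta(fa)
  dts <- unlist(lapply(reads, extract_ditags), use.names = FALSE)
  expect_equal(sort(dts), sort(em$ledger$ditags))
  # with planted duplicates, dedupe-on recovery equals the generator's
  # post-dedupe truth
  em2 <- emit_concatemers(lib, seed = 8, duplicate_rate = 0.1)
  fa2 <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(em2$reads), "\n", em2$reads), fa2)
  rec2 <- count_tags_fasta(fa2, dedupe = TRUE, library_id = "RT")
  expect_equal(rec2$counts[order(names(rec2$counts))],
               em2$ledger$tag_counts_post_dedupe[
                 order(names(em2$ledger$tag_counts_post_dedupe))])
})

test_that("tag table TSV round-trips with descending-count order", {
  lib <- tag_library(c(AAAAAAAAAA = 3, CCCCCCCCCC = 9, GGGGGGGGGG = 3))
  path <- tempfile(fileext = ".tsv")
  write_tag_counts(lib, path)
  txt <- readLines(path)
  expect_identical(txt[2L], "CCCCCCCCCC\t9")
  expect_identical(txt[3L], "AAAAAAAAAA\t3")  # tie broken lexicographically
  back <- read_tag_counts(path)
  expect_equal(back$counts[names(lib$counts)], lib$counts)
  expect_true(file.exists(paste0(path, ".json")))
})
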