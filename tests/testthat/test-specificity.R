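# In-silico PCR: site search vs naive scan, product geometry, classification,
# and the two-round filter.

test_that("a planted primer is found exactly where it was planted", {
  set.seed(41)
  primer <- random_dna_str(20)
  bg <- random_dna_str(10000)
  seq <- paste0(substr(bg, 1, 100), primer, substr(bg, 121, 10000))
  hits <- find_binding_sites(primer, c(s1 = seq), max_mismatch = 0L)
  planted <- hits[hits$start == 101L & hits$strand == "+", ]
  expect_identical(nrow(planted), 1L)
  expect_identical(planted$mismatches, 0L)
  # reverse-complement planting gives a minus-strand site
  seq2 <- paste0(substr(bg, 1, 100), oracle_revcomp(primer),
                 substr(bg, 121, 10000))
  hits2 <- find_binding_sites(primer, c(s1 = seq2), max_mismatch = 0L)
  planted2 <- hits2[hits2$start == 101L, ]
  expect_identical(planted2$strand, "-")
})

test_that("site search equals the naive Hamming scan", {
  set.seed(43)
  for (i in 1:8) {
    db <- c(s1 = random_dna_str(sample(2000:6000, 1L), gc = runif(1, 0.3, 0.7)))
    primer <- random_dna_str(sample(18:25, 1L))
    k <- sample(0:3, 1L)
    got <- as.data.frame(find_binding_sites(primer, db, max_mismatch = k))
    want <- naive_binding_sites(primer, db, k)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("primers containing N are rejected by the site search", {
  expect_error(find_binding_sites("ACGTNACGTACGTACGTA", c(s = "ACGT")), "DNA")
})

mk_site <- function(seq_id, start, end, strand, mm = 0L, mm3 = 0L) {
  tibble::tibble(seq_id = seq_id, start = start, end = end, strand = strand,
                 mismatches = mm, mismatches_3p = mm3)
}

test_that("products require convergent orientation, length cap, clean 3' ends", {
  fwd <- mk_site("s1", 11L, 30L, "+")
  rev <- mk_site("s1", 111L, 130L, "-")
  prods <- predict_products(fwd, rev, max_len = 5000L)
  expect_identical(nrow(prods), 1L)
  expect_identical(prods$length, 120L)
  expect_identical(prods$orientation, "fr")
  # same strand: nothing
  expect_identical(nrow(predict_products(fwd, mk_site("s1", 111L, 130L, "+"),
                                         5000L)), 0L)
  # too far apart: the length cap is a strict bound
  far <- mk_site("s1", 5011L, 5030L, "-") # product would be 5020 nt
  expect_identical(nrow(predict_products(fwd, far, 5000L)), 0L)
  expect_identical(nrow(predict_products(fwd, far, 5020L)), 1L)
  expect_identical(nrow(predict_products(fwd, mk_site("s1", 9111L, 9130L, "-"),
                                         5000L)), 0L)
  # 3' mismatch kills productivity
  expect_identical(nrow(predict_products(fwd, mk_site("s1", 111L, 130L, "-",
                                                      mm = 1L, mm3 = 1L),
                                         5000L)), 0L)
  # role-swapped orientation also amplifies
  swapped <- predict_products(mk_site("s1", 111L, 130L, "-"),
                              mk_site("s1", 11L, 30L, "+"), 5000L)
  expect_identical(swapped$orientation, "rf")
  expect_identical(swapped$length, 120L)
})

# a compact two-isoform gene plus decoy databases for screening tests
screening_fixture <- function(seed = 51) {
  locus <- generate_locus(locus_spec(seed = seed, plant_cdna_offtarget = TRUE))
  d <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- write_locus(locus, d)
  models <- read_gene_models(paths[["gtf"]], locus$genome)
  list(locus = locus, gm = models[["GENE1"]], genome = locus$genome)
}

test_that("product classification follows gene membership and target choice", {
  fx <- screening_fixture()
  gm <- fx$gm
  prods <- tibble::tibble(
    seq_id = c("T1", "T2", "DECOY_T1"),
    start = 1L, end = 100L, length = 100L, orientation = "fr",
    fwd_start = 1L, fwd_end = 20L, rev_start = 81L, rev_end = 100L,
    fwd_mismatches = 0L, rev_mismatches = 0L)
  got <- classify_products(prods, gm, targets = "T1", db = "cdna",
                           tx2gene = fx$locus$tx2gene)
  expect_identical(got$category,
                   c("on_target", "non_target_isoform", "off_target_gene"))
  expect_identical(
    classify_products(prods[1, ], gm, "T1", db = "genome")$category, "genomic")
  expect_error(classify_products(prods, gm, "T1", db = "cdna"),
               "unknown sequence id")
})

test_that("the two-round filter keeps clean pairs and rejects cdna off-targets", {
  fx <- screening_fixture()
  gm <- fx$gm
  tr <- gm$transcripts[["T1"]]
  cdna_db <- c(vapply(gm$transcripts, `[[`, "", "cdna"), fx$locus$decoys)
  # design on T1's private junction: clean; the decoy carries the shared
  # junction 1 neighbourhood, so pairs on junction 1 hit it
  clean <- generate_pairs(tr$cdna, tr$junctions[2],
                          design_params(max_candidates = 2L))
  dirty <- generate_pairs(tr$cdna, tr$junctions[1],
                          design_params(max_candidates = 2L))
  pairs <- dplyr::bind_rows(clean, dirty)
  screened <- two_round_filter(pairs, cdna_db, fx$genome, gm, targets = "T1",
                               tx2gene = fx$locus$tx2gene)
  expect_false(all(screened$all_pairs_flagged))
  clean_rows <- screened$n_off_target_gene == 0L
  expect_true(any(clean_rows) && any(!clean_rows))
  expect_true(all(screened$pass_round1[clean_rows]))
  expect_false(any(screened$pass_round1[!clean_rows]))
  # clean pairs rank first among round-1 survivors
  rows <- build_result_rows(screened)
  expect_true(all(rows$pass_round1[1:sum(clean_rows)]))
})

test_that("when every pair hits an off-target, all are retained and flagged", {
  fx <- screening_fixture()
  gm <- fx$gm
  tr <- gm$transcripts[["T1"]]
  cdna_db <- c(vapply(gm$transcripts, `[[`, "", "cdna"), fx$locus$decoys)
  pairs <- generate_pairs(tr$cdna, tr$junctions[1],
                          design_params(max_candidates = 4L))
  expect_gt(nrow(pairs), 0L)
  screened <- two_round_filter(pairs, cdna_db, fx$genome, gm, targets = "T1",
                               tx2gene = fx$locus$tx2gene)
  expect_true(all(screened$n_off_target_gene >= 1L))
  expect_true(all(screened$all_pairs_flagged))
  expect_true(all(screened$pass_round1))
})

test_that("a clean pair passes both rounds with exactly its on-target products", {
  fx <- screening_fixture()
  gm <- fx$gm
  tr <- gm$transcripts[["T1"]]
  cdna_db <- vapply(gm$transcripts, `[[`, "", "cdna")
  pairs <- generate_pairs(tr$cdna, tr$junctions[2],
                          design_params(max_candidates = 5000L))
  # a forward-spanning pair with generous overhangs on both sides: its 3'
  # terminus crosses the junction (no genomic extension) and its 5' tail is
  # long enough to discriminate isoforms lacking the junction
  pairs <- utils::head(pairs[pairs$spans == "forward" &
                               pairs$overlap_5p >= 8L &
                               pairs$overlap_3p >= 8L, ], 1L)
  expect_identical(nrow(pairs), 1L)
  screened <- two_round_filter(pairs, cdna_db, fx$genome, gm, targets = "T1")
  expect_true(screened$pass_round1[1])
  expect_true(screened$pass_round2[1])
  prods <- screened$products[[1]]
  expect_identical(sort(unique(prods$category)), "on_target")
  # junction 2 of T1 is private, so exactly one product on T1
  expect_identical(nrow(prods), 1L)
  expect_identical(prods$seq_id, "T1")
  # productive sites never appear among the unproductive leftovers
  up <- screened$unproductive_hits[[1]]
  expect_false(any(paste(up$seq_id, up$start, up$end) %in%
                     paste(prods$seq_id, prods$fwd_start, prods$fwd_end)))
})

test_that("product counts are invariant under database reordering", {
  fx <- screening_fixture()
  gm <- fx$gm
  tr <- gm$transcripts[["T1"]]
  cdna_db <- c(vapply(gm$transcripts, `[[`, "", "cdna"), fx$locus$decoys)
  pairs <- generate_pairs(tr$cdna, tr$junctions[1],
                          design_params(max_candidates = 2L))
  a <- two_round_filter(pairs, cdna_db, fx$genome, gm, "T1",
                        tx2gene = fx$locus$tx2gene)
  b <- two_round_filter(pairs, rev(cdna_db), fx$genome, gm, "T1",
                        tx2gene = fx$locus$tx2gene)
  expect_identical(a$n_on_target, b$n_on_target)
  expect_identical(a$n_off_target_gene, b$n_off_target_gene)
  expect_identical(a$n_genomic, b$n_genomic)
})
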