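# Discriminating-junction selection: perfect sets, fallback ranking,
# warnings, and the incidence matrix.

# two-isoform toy shared/private junction gene (T1: J1,J2 ; T2: J1,J3)
toy_two_isoform <- function() {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  genome <- c(chr1 = random_dna_str(600))
  rows <- c(
    'chr1\tx\texon\t1\t50\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tx\texon\t101\t150\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tx\texon\t201\t250\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tx\texon\t1\t50\t.\t+\t.\tgene_id "G1"; transcript_id "T2";',
    'chr1\tx\texon\t101\t150\t.\t+\t.\tgene_id "G1"; transcript_id "T2";',
    'chr1\tx\texon\t301\t350\t.\t+\t.\tgene_id "G1"; transcript_id "T2";'
  )
  gtf <- file.path(d, "g.gtf"); fa <- file.path(d, "g.fa")
  writeLines(rows, gtf)
  writeLines(c(">chr1", unname(genome)), fa)
  read_gene_models(gtf, fa)[["G1"]]
}

test_that("perfect junctions are exactly those covering targets and nothing else", {
  gm <- toy_two_isoform()
  # both isoforms selected: only the shared junction qualifies
  sel <- select_junctions(gm, c("T1", "T2"))
  expect_true(sel$perfect)
  expect_identical(nrow(sel$junctions), 1L)
  expect_identical(sel$junctions$donor, 50L)
  expect_identical(nrow(sel$warnings), 0L)
  # T1 alone: its private junction, because the shared one leaks into T2
  sel1 <- select_junctions(gm, "T1")
  expect_true(sel1$perfect)
  expect_identical(sel1$junctions$acceptor, 201L)
})

test_that("with no perfect junction all are ranked and warnings are emitted", {
  d <- withr::local_tempdir()
  # T1 and T2 share their single junction; targeting T1 alone cannot be perfect
  rows <- c(
    'chr1\tx\texon\t1\t50\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tx\texon\t101\t150\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tx\texon\t1\t50\t.\t+\t.\tgene_id "G1"; transcript_id "T2";',
    'chr1\tx\texon\t101\t150\t.\t+\t.\tgene_id "G1"; transcript_id "T2";'
  )
  gtf <- file.path(d, "g.gtf"); fa <- file.path(d, "g.fa")
  writeLines(rows, gtf); writeLines(c(">chr1", random_dna_str(300)), fa)
  gm <- read_gene_models(gtf, fa)[["G1"]]
  sel <- select_junctions(gm, "T1")
  expect_false(sel$perfect)
  expect_identical(nrow(sel$junctions), 1L)
  expect_identical(sel$warnings$transcript_id, "T2")
  expect_identical(sel$warnings$kind, "non_targeted_detected")
})

test_that("degenerate requests fail loudly", {
  gm <- toy_two_isoform()
  expect_error(select_junctions(gm, character(0)), "non-empty")
  expect_error(select_junctions(gm, "T9"), "T9")
  d <- withr::local_tempdir()
  writeLines('chr1\tx\texon\t1\t50\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
             file.path(d, "g.gtf"))
  writeLines(c(">chr1", random_dna_str(100)), file.path(d, "g.fa"))
  single <- read_gene_models(file.path(d, "g.gtf"), file.path(d, "g.fa"))[["G1"]]
  expect_error(select_junctions(single, "T1"), "single-exon")
})

test_that("junction matrix matches per-transcript junction counts", {
  gm <- toy_two_isoform()
  m <- junction_matrix(gm)
  expect_identical(dim(m), c(3L, 2L))
  n_exons <- vapply(gm$transcripts, function(t) nrow(t$exons), integer(1))
  expect_identical(unname(colSums(m)), unname(n_exons[colnames(m)] - 1))
})

test_that("selection matches the brute-force oracle on random gene models", {
  lg <- load_random_genes(25, seed = 101)
  for (sp in lg$specs) {
    gm <- lg$models[[sp$gene_id]]
    subsets <- unlist(lapply(seq_along(sp$tx_ids), function(k)
      utils::combn(sp$tx_ids, k, simplify = FALSE)), recursive = FALSE)
    for (targets in subsets) {
      sel <- select_junctions(gm, targets)
      got <- if (sel$perfect)
        paste(sel$junctions$donor, sel$junctions$acceptor, sep = "_") else
        character(0)
      expect_setequal(got, oracle_perfect_set(sp$incidence, sp$tx_ids, targets))
    }
  }
})

test_that("every junction is perfect exactly for its own incidence set", {
  # a junction covering transcript set S is a perfect junction for target
  # set S and for no other target set
  lg <- load_random_genes(10, seed = 202)
  for (sp in lg$specs) {
    gm <- lg$models[[sp$gene_id]]
    for (key in names(sp$incidence)) {
      sel <- select_junctions(gm, sp$incidence[[key]])
      expect_true(sel$perfect)
      expect_true(key %in% paste(sel$junctions$donor, sel$junctions$acceptor,
                                 sep = "_"))
    }
  }
})

test_that("selecting every transcript leaves zero leakage everywhere", {
  lg <- load_random_genes(10, seed = 303)
  for (sp in lg$specs) {
    gm <- lg$models[[sp$gene_id]]
    sel <- select_junctions(gm, "ALL")
    common <- names(Filter(function(tx) setequal(tx, sp$tx_ids), sp$incidence))
    if (length(common) > 0L) {
      expect_true(sel$perfect)
      expect_setequal(paste(sel$junctions$donor, sel$junctions$acceptor,
                            sep = "_"), common)
    } else {
      expect_false(sel$perfect)
    }
    expect_true(all(sel$junctions$leakage == 0L))
  }
})
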