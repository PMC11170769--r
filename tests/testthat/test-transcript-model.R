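# Spliced cDNA construction, junction enumeration, annotation and custom
# transcript input.

toy_genome <- c(chr1 = "AAACCCGGGTTT")

toy_exons <- function(strand) {
  ex <- tibble::tibble(chrom = "chr1", start = c(1L, 7L), end = c(3L, 9L),
                       strand = strand, rank = 1:2)
  if (strand == "-") ex$rank <- 2:1
  ex
}

test_that("build_cdna splices plus-strand exons in coordinate order", {
  sp <- build_cdna(toy_exons("+"), toy_genome)
  expect_identical(sp$cdna, "AAAGGG")
  expect_identical(sp$junctions, 3L)
})

test_that("build_cdna reverse-complements minus-strand exons", {
  # manual oracle: revcomp("GGG") + revcomp("AAA") = "CCC" + "TTT"
  sp <- build_cdna(toy_exons("-"), toy_genome)
  expect_identical(sp$cdna, "CCCTTT")
  expect_identical(sp$junctions, 3L)
})

test_that("single exon yields no junction; bad exons are fatal", {
  sp <- build_cdna(tibble::tibble(chrom = "chr1", start = 1L, end = 6L,
                                  strand = "+", rank = 1L), toy_genome)
  expect_identical(sp$cdna, "AAACCC")
  expect_identical(sp$junctions, integer(0))
  expect_error(build_cdna(tibble::tibble(chrom = "chr1", start = 1L, end = 99L,
                                         strand = "+", rank = 1L), toy_genome),
               "bounds")
  expect_error(build_cdna(toy_exons("+")[0, ], toy_genome), "zero exons")
})

test_that("cutting the cdna at junctions reproduces per-exon sequences", {
  set.seed(21)
  for (i in 1:20) {
    n_ex <- sample(2:5, 1L)
    lens <- sample(10:40, n_ex, replace = TRUE)
    gaps <- sample(5:20, n_ex - 1L, replace = TRUE)
    starts <- cumsum(c(1L, utils::head(lens, -1L) + gaps))
    ends <- starts + lens - 1L
    strand <- sample(c("+", "-"), 1L)
    chrom_seq <- random_dna_str(max(ends) + 10L)
    genome <- c(chrZ = chrom_seq)
    rank <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    ex <- tibble::tibble(chrom = "chrZ", start = starts, end = ends,
                         strand = strand, rank = rank)
    sp <- build_cdna(ex, genome)
    bounds <- c(0L, sp$junctions, nchar(sp$cdna))
    pieces <- substring(sp$cdna, utils::head(bounds, -1L) + 1L, bounds[-1L])
    genomic <- substring(chrom_seq, starts, ends)
    expected <- if (strand == "+") genomic else
      rev(vapply(genomic, oracle_revcomp, "", USE.NAMES = FALSE))
    expect_identical(pieces, expected)
    # strand symmetry: mirrored coordinates on the reverse-complemented
    # chromosome give the same cdna
    L <- nchar(chrom_seq)
    mirrored <- tibble::tibble(
      chrom = "chrZ", start = L - ends + 1L, end = L - starts + 1L,
      strand = if (strand == "+") "-" else "+", rank = rank)
    sp2 <- build_cdna(mirrored, c(chrZ = oracle_revcomp(chrom_seq)))
    expect_identical(sp2$cdna, sp$cdna)
  }
})

write_mini_annotation <- function(dir, gtf_lines, genome) {
  gtf <- file.path(dir, "mini.gtf")
  fa <- file.path(dir, "mini.fa")
  writeLines(gtf_lines, gtf)
  writeLines(c(paste0(">", names(genome)), unname(genome)), fa)
  list(gtf = gtf, fa = fa)
}

test_that("annotation loading builds models, ignores row order, picks canonical", {
  d <- withr::local_tempdir()
  genome <- c(chr1 = random_dna_str(400))
  rows <- c(
    'chr1\tx\texon\t1\t50\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tx\texon\t101\t150\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tx\texon\t1\t50\t.\t+\t.\tgene_id "G1"; transcript_id "T2";',
    'chr1\tx\texon\t101\t150\t.\t+\t.\tgene_id "G1"; transcript_id "T2";',
    'chr1\tx\texon\t201\t260\t.\t+\t.\tgene_id "G1"; transcript_id "T2";'
  )
  p <- write_mini_annotation(d, rows, genome)
  models <- read_gene_models(p$gtf, p$fa)
  gm <- models[["G1"]]
  expect_length(gm$transcripts, 2L)
  expect_identical(length(gm$transcripts[["T1"]]$junctions), 1L)
  # canonical fallback: longest cdna wins
  expect_identical(gm$canonical_id, "T2")
  # shuffled exon rows give the identical result
  p2 <- write_mini_annotation(withr::local_tempdir(), rev(rows), genome)
  models2 <- read_gene_models(p2$gtf, p2$fa)
  expect_identical(models2[["G1"]]$transcripts[["T2"]]$cdna,
                   gm$transcripts[["T2"]]$cdna)
  expect_identical(models2[["G1"]]$transcripts[["T2"]]$junctions,
                   gm$transcripts[["T2"]]$junctions)
})

test_that("canonical tag beats the length fallback; missing chromosome is fatal", {
  d <- withr::local_tempdir()
  genome <- c(chr1 = random_dna_str(400))
  rows <- c(
    paste0('chr1\tx\texon\t1\t50\t.\t+\t.\tgene_id "G1"; transcript_id "T1"; ',
           'tag "Ensembl_canonical";'),
    'chr1\tx\texon\t101\t150\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tx\texon\t1\t50\t.\t+\t.\tgene_id "G1"; transcript_id "T2";',
    'chr1\tx\texon\t101\t260\t.\t+\t.\tgene_id "G1"; transcript_id "T2";'
  )
  p <- write_mini_annotation(d, rows, genome)
  expect_identical(read_gene_models(p$gtf, p$fa)[["G1"]]$canonical_id, "T1")
  bad <- c('chrMISSING\tx\texon\t1\t50\t.\t+\t.\tgene_id "G2"; transcript_id "T9";')
  p2 <- write_mini_annotation(withr::local_tempdir(), bad, genome)
  expect_error(read_gene_models(p2$gtf, p2$fa), "chrMISSING.*T9")
})

test_that("junction enumeration maps junctions to exactly their transcripts", {
  d <- withr::local_tempdir()
  genome <- c(chr1 = random_dna_str(500))
  rows <- c(
    # T1: exons 1,2,3 ; T2: exons 1,2,4 (shared junction 1-2)
    'chr1\tx\texon\t1\t50\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tx\texon\t101\t150\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tx\texon\t201\t250\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tx\texon\t1\t50\t.\t+\t.\tgene_id "G1"; transcript_id "T2";',
    'chr1\tx\texon\t101\t150\t.\t+\t.\tgene_id "G1"; transcript_id "T2";',
    'chr1\tx\texon\t301\t350\t.\t+\t.\tgene_id "G1"; transcript_id "T2";'
  )
  p <- write_mini_annotation(d, rows, genome)
  gm <- read_gene_models(p$gtf, p$fa)[["G1"]]
  jx <- enumerate_junctions(gm)
  expect_identical(nrow(jx), 3L)
  shared <- jx[jx$donor == 50L & jx$acceptor == 101L, ]
  expect_setequal(shared$transcript_ids[[1L]], c("T1", "T2"))
  expect_identical(jx$transcript_ids[[which(jx$acceptor == 201L)]], "T1")
  expect_identical(jx$transcript_ids[[which(jx$acceptor == 301L)]], "T2")
  # single transcript with 3 exons: 2 junctions, each on that transcript
  gm1 <- read_gene_models(write_mini_annotation(
    withr::local_tempdir(), rows[1:3], genome)$gtf, p$fa)[["G1"]]
  jx1 <- enumerate_junctions(gm1)
  expect_identical(nrow(jx1), 2L)
  expect_true(all(vapply(jx1$transcript_ids, identical, logical(1), y = "T1")))
})

test_that("custom FASTA transcripts parse the junctions= header token", {
  d <- withr::local_tempdir()
  fa <- file.path(d, "custom.fa")
  seq <- random_dna_str(500)
  writeLines(c(">seq1 junctions=119,339", seq), fa)
  tr <- parse_custom_transcript(fa)
  # 0-based offsets in the header become 1-based last-base positions
  expect_identical(tr$junctions, c(120L, 340L))
  expect_identical(tr$gene_id, "seq1")
  expect_true(tr$is_canonical)
  expect_identical(nchar(tr$cdna), 500L)

  writeLines(c(">seq1 junctions=600", seq), fa)
  expect_error(parse_custom_transcript(fa), "out of range")
  writeLines(c(">seq1 junctions=12.5", seq), fa)
  expect_error(parse_custom_transcript(fa), "non-integer")
  writeLines(c(">seq1 some description", seq), fa)
  expect_warning(tr2 <- parse_custom_transcript(fa), "junctions=")
  expect_identical(tr2$junctions, integer(0))
})

test_that("GenBank exon features define junctions by boundary arithmetic", {
  d <- withr::local_tempdir()
  gb <- file.path(d, "custom.gb")
  seq <- tolower(random_dna_str(250))
  seq_lines <- vapply(seq(1L, 250L, 60L), function(i)
    paste0("      ", i, " ", substr(seq, i, min(i + 59L, 250L))), "")
  writeLines(c(
    "LOCUS       SEQGB1   250 bp    DNA     linear   01-JAN-2024",
    "FEATURES             Location/Qualifiers",
    "     exon            1..100",
    "     exon            101..250",
    "ORIGIN",
    seq_lines,
    "//"
  ), gb)
  tr <- parse_custom_transcript(gb)
  expect_identical(tr$junctions, 100L)
  expect_identical(tr$cdna, toupper(seq))
  expect_identical(tr$transcript_id, "SEQGB1")
  gm <- as_gene_model(tr)
  expect_identical(gm$canonical_id, "SEQGB1")
})

test_that("genomes with non-N ambiguity codes are rejected", {
  d <- withr::local_tempdir()
  fa <- file.path(d, "amb.fa")
  writeLines(c(">c1", "ACGTRYACGT"), fa)
  expect_error(read_genome(fa), "ambiguity")
  writeLines(c(">c1", "ACGTNNACGT"), fa)
  expect_identical(unname(read_genome(fa)), "ACGTNNACGT")
})
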