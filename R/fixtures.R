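# Seeded synthetic loci with exact ground truth: a multi-isoform gene on one
# chromosome, common variants straddling the masking threshold, and optional
# planted off-targets (an intron-less processed-pseudogene copy in the
# genome, and a decoy "other gene" transcript sharing a junction window).
#
# All randomness flows through one seeded RNG; the same spec yields
# byte-identical files.

#' Specification of a synthetic test locus
#'
#' The generated gene has `n_exons + 1` exon slots; isoform k uses slots 1
#' and 2 plus all later slots except slot `2 + k`, so every isoform shares
#' the first junction and owns at least one private (exon-skipping) junction.
#'
#' @param seed Integer seed; fully determines the output.
#' @param n_isoforms Number of isoforms (default 3; at most `n_exons - 2`).
#' @param n_exons Exons per isoform (default 6, valid 4-8).
#' @param exon_len Exon length range in nt (default 80-300).
#' @param intron_len Intron length range in nt (default 500-5000).
#' @param gc_bias Background GC fraction of generated sequence (default 0.5).
#'   A 0.60-GC window of `junction_gc_width` nt is injected on both sides of
#'   every exon boundary so that junction-anchored design is feasible at
#'   default thermodynamic parameters.
#' @param junction_gc_width Width of the injected GC-balanced window (default
#'   40 nt).
#' @param n_common_variants Number of variant records written to the VCF;
#'   allele frequencies cycle through values straddling the 1% threshold, and
#'   one record is a multi-base deletion (default 6).
#' @param plant_pseudogene Insert an intron-less copy of the canonical cDNA
#'   elsewhere on the chromosome.
#' @param plant_cdna_offtarget Add a decoy other-gene transcript containing
#'   the target's first-junction neighbourhood verbatim.
#' @param chrom Chromosome name (default `"chrS"`).
#' @param flank Plain-sequence padding at the chromosome ends (default 1000).
#' @return A `locus_spec` list.
#' @export
locus_spec <- function(seed, n_isoforms = 3L, n_exons = 6L,
                       exon_len = c(80L, 300L), intron_len = c(500L, 5000L),
                       gc_bias = 0.5, junction_gc_width = 40L,
                       n_common_variants = 6L, plant_pseudogene = FALSE,
                       plant_cdna_offtarget = FALSE, chrom = "chrS",
                       flank = 1000L) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (n_exons < 4L || n_exons > 8L) stop("n_exons must be in 4..8", call. = FALSE)
  if (n_isoforms < 1L || n_isoforms > n_exons - 2L) {
    stop("n_isoforms must be in 1..(n_exons - 2)", call. = FALSE)
  }
  stopifnot(exon_len[1] >= 40L, exon_len[1] <= exon_len[2],
            intron_len[1] >= 1L, intron_len[1] <= intron_len[2],
            gc_bias > 0, gc_bias < 1)
  structure(
    list(seed = as.integer(seed), n_isoforms = as.integer(n_isoforms),
         n_exons = as.integer(n_exons), exon_len = as.integer(exon_len),
         intron_len = as.integer(intron_len), gc_bias = gc_bias,
         junction_gc_width = as.integer(junction_gc_width),
         n_common_variants = as.integer(n_common_variants),
         plant_pseudogene = isTRUE(plant_pseudogene),
         plant_cdna_offtarget = isTRUE(plant_cdna_offtarget),
         chrom = chrom, flank = as.integer(flank)),
    class = "locus_spec"
  )
}

.random_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# exon sequence with GC-balanced windows at both ends (junction vicinity)
.exon_seq <- function(len, spec) {
  w <- min(spec$junction_gc_width, len %/% 2L)
  mid <- len - 2L * w
  paste0(.random_dna(w, 0.60), .random_dna(mid, spec$gc_bias),
         .random_dna(w, 0.60))
}

# TRUE when the sequence context left|right admits at least one
# junction-crossing primer at default design parameters
.has_crossing_candidate <- function(left, right,
                                    params = design_params()) {
  ctx <- paste0(left, right)
  j <- nchar(left)
  w <- .span_forward_windows(j, params)
  sc <- .screen_candidates(ctx, w$start, w$end, "forward", params)
  nrow(sc$candidates) > 0L
}

# redraw the leading window of an exon until every junction ending at it
# (from each plausible upstream donor) admits a crossing primer; this makes
# the generator's feasibility guarantee constructive rather than hoped-for
.draw_left_window <- function(donor_tails, w, max_tries = 60L) {
  for (i in seq_len(max_tries)) {
    cand <- .random_dna(w, 0.60)
    ok <- all(vapply(donor_tails, .has_crossing_candidate, logical(1),
                     right = cand))
    if (ok) return(cand)
  }
  cand
}

#' Generate a synthetic locus with ground truth
#'
#' @param spec A [locus_spec()].
#' @return A `synthetic_locus` list: `genome` (named vector), `gtf_lines`,
#'   `vcf_lines`, `decoys` (named vector, possibly empty), `tx2gene`,
#'   `exon_table` (tibble of all exon records), and `truth` with
#'   `junction_matrix`, `masked` (tibble `chrom`,`pos`), `variants` tibble,
#'   `pseudogene` coordinates (or `NULL`), `decoy` info (or `NULL`), and the
#'   seed. Same spec, same output, byte for byte.
#' @export
generate_locus <- function(spec) {
  stopifnot(inherits(spec, "locus_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  M <- spec$n_exons + (if (spec$n_isoforms > 1L) 1L else 0L)
  exon_lens <- sample(spec$exon_len[1]:spec$exon_len[2], M, replace = TRUE)
  if (spec$plant_cdna_offtarget) {
    # the decoy copies the +/-250 nt window around the shared first junction;
    # the flanking exons must contain it so the window never crosses a
    # neighbouring (private) junction and holds any qPCR-sized amplicon
    exon_lens[1:2] <- pmax(exon_lens[1:2], 260L)
  }
  intron_lens <- sample(spec$intron_len[1]:spec$intron_len[2], M - 1L,
                        replace = TRUE)
  exon_seqs <- vapply(exon_lens, .exon_seq, "", spec = spec)
  # guarantee every realizable junction (consecutive and single-exon-skip
  # pairs) admits at least one spanning primer at default parameters
  for (k in 2:M) {
    w <- min(spec$junction_gc_width, exon_lens[k] %/% 2L)
    donors <- lapply(max(1L, k - 2L):(k - 1L), function(d) {
      wd <- min(spec$junction_gc_width, exon_lens[d] %/% 2L)
      substr(exon_seqs[d], exon_lens[d] - wd + 1L, exon_lens[d])
    })
    left <- .draw_left_window(donors, w)
    exon_seqs[k] <- paste0(left, substr(exon_seqs[k], w + 1L, exon_lens[k]))
  }

  # genomic layout: flank, exon/intron alternation, flank
  pos <- spec$flank + 1L
  starts <- integer(M); ends <- integer(M)
  pieces <- list(.random_dna(spec$flank, spec$gc_bias))
  for (k in seq_len(M)) {
    starts[k] <- pos
    ends[k] <- pos + exon_lens[k] - 1L
    pieces[[length(pieces) + 1L]] <- exon_seqs[k]
    pos <- ends[k] + 1L
    if (k < M) {
      pieces[[length(pieces) + 1L]] <- .random_dna(intron_lens[k], spec$gc_bias)
      pos <- pos + intron_lens[k]
    }
  }
  pieces[[length(pieces) + 1L]] <- .random_dna(spec$flank, spec$gc_bias)

  # isoform k skips exon slot 2 + k (single-isoform genes use all slots)
  iso_slots <- lapply(seq_len(spec$n_isoforms), function(k) {
    if (spec$n_isoforms == 1L) seq_len(M) else setdiff(seq_len(M), 2L + k)
  })
  tx_ids <- sprintf("T%d", seq_len(spec$n_isoforms))

  exon_table <- dplyr::bind_rows(lapply(seq_along(iso_slots), function(k) {
    slots <- iso_slots[[k]]
    tibble(chrom = spec$chrom, start = starts[slots], end = ends[slots],
           strand = "+", rank = seq_along(slots), transcript_id = tx_ids[k],
           gene_id = "GENE1", slot = slots)
  }))

  # ground-truth junction incidence, by direct construction
  jx_per_tx <- lapply(iso_slots, function(slots) {
    up <- slots[-length(slots)]; dn <- slots[-1L]
    tibble(donor = ends[up], acceptor = starts[dn])
  })
  all_jx <- dplyr::distinct(dplyr::bind_rows(jx_per_tx)) |>
    dplyr::arrange(.data$donor, .data$acceptor)
  jmat <- matrix(0L, nrow = nrow(all_jx), ncol = length(tx_ids),
                 dimnames = list(.junction_label(spec$chrom, all_jx$donor,
                                                 all_jx$acceptor, "+"),
                                 tx_ids))
  for (k in seq_along(jx_per_tx)) {
    hit <- paste(jx_per_tx[[k]]$donor, jx_per_tx[[k]]$acceptor) %in%
      paste(all_jx$donor, all_jx$acceptor)
    stopifnot(all(hit))
    jmat[match(paste(jx_per_tx[[k]]$donor, jx_per_tx[[k]]$acceptor),
               paste(all_jx$donor, all_jx$acceptor)), k] <- 1L
  }

  # variants: exonic SNPs with AFs straddling the threshold, plus one
  # deletion; positions keep clear of exon ends so some primer windows
  # always survive masking
  afs <- c(0.05, 0.002, 0.01, 0.005, 0.20, 0.008)
  variants <- NULL
  if (spec$n_common_variants > 0L) {
    margin <- 45L
    pool <- unlist(lapply(seq_len(M), function(k) {
      if (ends[k] - starts[k] + 1L > 2L * margin + 10L)
        (starts[k] + margin):(ends[k] - margin) else integer(0)
    }))
    vpos <- sort(sample(pool, min(spec$n_common_variants, length(pool))))
    variants <- tibble(
      chrom = spec$chrom, pos = vpos,
      af = rep_len(afs, length(vpos)),
      ref_len = c(3L, rep(1L, length(vpos) - 1L)) # first record is a deletion
    )
  }

  cdna_for <- function(slots) paste(exon_seqs[slots], collapse = "")
  canonical_cdna <- cdna_for(iso_slots[[1L]])

  pseudo <- NULL
  if (spec$plant_pseudogene) {
    pieces[[length(pieces) + 1L]] <- .random_dna(2000L, spec$gc_bias)
    pieces[[length(pieces) + 1L]] <- canonical_cdna
    pieces[[length(pieces) + 1L]] <- .random_dna(spec$flank, spec$gc_bias)
  }
  genome_str <- paste(unlist(pieces), collapse = "")
  if (spec$plant_pseudogene) {
    pstart <- nchar(genome_str) - spec$flank - nchar(canonical_cdna) + 1L
    pseudo <- list(start = pstart, end = pstart + nchar(canonical_cdna) - 1L,
                   source_transcript = tx_ids[1L], type = "processed_pseudogene")
  }
  genome <- setNames(genome_str, spec$chrom)

  decoys <- setNames(character(0), character(0))
  tx2gene <- character(0)
  decoy_info <- NULL
  if (spec$plant_cdna_offtarget) {
    j1 <- exon_lens[1L] # cDNA position of the shared first junction
    lo <- max(1L, j1 - 250L)
    hi <- min(nchar(canonical_cdna), j1 + 250L)
    shared <- substr(canonical_cdna, lo, hi)
    decoy_seq <- paste0(.random_dna(300L, spec$gc_bias), shared,
                        .random_dna(300L, spec$gc_bias))
    decoys <- c(DECOY_T1 = decoy_seq)
    tx2gene <- c(DECOY_T1 = "DECOYG")
    decoy_info <- list(id = "DECOY_T1", gene = "DECOYG",
                       copied_from = c(lo, hi), insert_at = 301L)
  }

  # variant truth: REF footprint positions of records at/above threshold
  masked <- tibble(chrom = character(), pos = integer())
  vcf_lines <- c("##fileformat=VCFv4.2",
                 sprintf("##seed=%d", spec$seed),
                 "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
                 paste0("##contig=<ID=", spec$chrom, ">"),
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (!is.null(variants) && nrow(variants) > 0L) {
    for (i in seq_len(nrow(variants))) {
      p <- variants$pos[i]; rl <- variants$ref_len[i]
      ref <- substr(genome_str, p, p + rl - 1L)
      alt <- if (rl > 1L) substr(ref, 1L, 1L) else
        setdiff(c("A", "C", "G", "T"), substr(ref, 1L, 1L))[1L]
      vcf_lines <- c(vcf_lines,
                     sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%s",
                             spec$chrom, p, ref, alt,
                             format(variants$af[i], scientific = FALSE)))
      if (variants$af[i] >= 0.01) {
        masked <- dplyr::bind_rows(masked,
                                   tibble(chrom = spec$chrom,
                                          pos = p:(p + rl - 1L)))
      }
    }
  }
  masked <- dplyr::distinct(dplyr::arrange(masked, .data$pos))

  gtf_lines <- c(sprintf("#!seed %d", spec$seed))
  for (k in seq_along(iso_slots)) {
    slots <- iso_slots[[k]]
    for (r in seq_along(slots)) {
      attrs <- sprintf(paste0('gene_id "GENE1"; transcript_id "%s"; ',
                              'gene_name "SYNGENE"; exon_number "%d";'),
                       tx_ids[k], r)
      if (k == 1L) attrs <- paste0(attrs, ' tag "Ensembl_canonical";')
      gtf_lines <- c(gtf_lines,
                     paste(spec$chrom, "synthetic", "exon", starts[slots[r]],
                           ends[slots[r]], ".", "+", ".", attrs, sep = "\t"))
    }
  }

  structure(
    list(spec = spec, genome = genome, gtf_lines = gtf_lines,
         vcf_lines = vcf_lines, decoys = decoys, tx2gene = tx2gene,
         exon_table = exon_table,
         truth = list(seed = spec$seed, junction_matrix = jmat,
                      masked = masked, variants = variants,
                      pseudogene = pseudo, decoy = decoy_info,
                      shared_junction_cdna_pos = exon_lens[1L],
                      exon_starts = starts, exon_ends = ends,
                      iso_slots = iso_slots)),
    class = "synthetic_locus"
  )
}

#' @export
print.synthetic_locus <- function(x, ...) {
  cat("<synthetic_locus> seed ", x$spec$seed, ": ", x$spec$n_isoforms,
      " isoforms, genome ", nchar(x$genome), " nt",
      if (!is.null(x$truth$pseudogene)) ", pseudogene planted",
      if (!is.null(x$truth$decoy)) ", cDNA decoy planted", "\n", sep = "")
  invisible(x)
}

#' Write a synthetic locus to disk
#'
#' Emits `genome.fa`, `annotation.gtf`, `common.vcf`, `decoys.fa` (when a
#' decoy was planted) and `truth.json` into `dir`. Identical loci write
#' byte-identical files.
#'
#' @param locus A `synthetic_locus` from [generate_locus()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_locus <- function(locus, dir) {
  stopifnot(inherits(locus, "synthetic_locus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             gtf = file.path(dir, "annotation.gtf"),
             vcf = file.path(dir, "common.vcf"),
             truth = file.path(dir, "truth.json"))
  seed <- locus$spec$seed
  fa <- c(sprintf(">%s seed=%d", names(locus$genome), seed),
          .wrap_fasta(locus$genome[[1L]]))
  writeLines(fa, paths[["genome"]])
  writeLines(locus$gtf_lines, paths[["gtf"]])
  writeLines(locus$vcf_lines, paths[["vcf"]])
  if (length(locus$decoys) > 0L) {
    paths <- c(paths, decoys = file.path(dir, "decoys.fa"))
    dl <- unlist(lapply(names(locus$decoys), function(id) {
      c(sprintf(">%s seed=%d gene=%s", id, seed, locus$tx2gene[[id]]),
        .wrap_fasta(locus$decoys[[id]]))
    }))
    writeLines(dl, paths[["decoys"]])
  }
  truth <- locus$truth
  truth$junction_matrix <- list(
    junctions = rownames(truth$junction_matrix),
    transcripts = colnames(truth$junction_matrix),
    matrix = unname(apply(truth$junction_matrix, 1L, as.integer,
                          simplify = FALSE))
  )
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(paths)
}

.wrap_fasta <- function(seq, width = 70L) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, width), pmin(seq(1L, n, width) + width - 1L, n))
}
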