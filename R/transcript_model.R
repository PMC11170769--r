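# Gene/transcript models: spliced cDNA construction and junction enumeration.
#
# Genomic coordinates are 1-based inclusive throughout (the Bioconductor
# convention); GTF/GFF is already 1-based so import is direct. A transcript's
# `junctions` vector holds the 1-based cDNA position of the last base of each
# upstream exon, so junction k sits between cDNA positions junctions[k] and
# junctions[k] + 1.

#' Read a genome FASTA into a named vector of chromosome sequences
#'
#' @param fasta Path to a (multi-)FASTA file.
#' @return Named character vector, uppercase, one element per chromosome.
#'   Ambiguity letters other than `N` are rejected: downstream thermodynamic
#'   tables are defined over A/C/G/T only.
#' @export
read_genome <- function(fasta) {
  ss <- Biostrings::readDNAStringSet(fasta)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs))) stop("duplicate chromosome names in FASTA", call. = FALSE)
  if (any(nchar(seqs) == 0L)) stop("empty sequence in FASTA", call. = FALSE)
  bad <- !grepl("^[ACGTN]+$", seqs)
  if (any(bad)) {
    stop("chromosome ", names(seqs)[bad][1L],
         " contains ambiguity letters other than N", call. = FALSE)
  }
  seqs
}

#' Construct a transcript model
#'
#' Low-level constructor used by the annotation loaders; exported so models
#' can also be built directly from an exon table (e.g. one produced by a
#' synthetic-locus generator) together with [build_cdna()].
#'
#' @param transcript_id,gene_id Identifiers.
#' @param exons Tibble with `chrom`, `start`, `end`, `strand`, `rank`.
#' @param cdna Spliced cDNA string.
#' @param junctions Integer vector: 1-based cDNA position of the last base of
#'   each upstream exon.
#' @param is_canonical Canonical flag.
#' @return A `transcript_model`.
#' @export
new_transcript_model <- function(transcript_id, gene_id, exons, cdna, junctions,
                                 is_canonical = FALSE) {
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, exons = exons,
         cdna = cdna, junctions = as.integer(junctions),
         is_canonical = isTRUE(is_canonical)),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", x$transcript_id, " (gene ", x$gene_id, ")",
      if (x$is_canonical) " [canonical]", "\n", sep = "")
  cat("  ", nrow(x$exons), " exons, cDNA ", nchar(x$cdna), " nt, ",
      length(x$junctions), " junctions\n", sep = "")
  invisible(x)
}

#' Construct a gene model from transcript models
#'
#' @param gene_id,gene_name Identifiers.
#' @param transcripts List of `transcript_model`s; exactly one must carry
#'   `is_canonical = TRUE`.
#' @return A `gene_model`.
#' @export
new_gene_model <- function(gene_id, gene_name, transcripts) {
  canon <- vapply(transcripts, function(t) t$is_canonical, logical(1))
  if (sum(canon) != 1L) stop("gene ", gene_id, " must have exactly one canonical transcript",
                             call. = FALSE)
  structure(
    list(gene_id = gene_id, gene_name = gene_name,
         transcripts = setNames(transcripts,
                                vapply(transcripts, `[[`, "", "transcript_id")),
         canonical_id = transcripts[[which(canon)]]$transcript_id),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_id,
      if (nzchar(x$gene_name) && !identical(x$gene_name, x$gene_id))
        paste0(" (", x$gene_name, ")"),
      ": ", length(x$transcripts), " transcripts, canonical ",
      x$canonical_id, "\n", sep = "")
  invisible(x)
}

#' Build a spliced cDNA from an exon table
#'
#' Concatenates exon genomic sequence in transcription order: ascending
#' coordinate on `+`, reverse-complemented exons in descending coordinate
#' order on `-`.
#'
#' @param exons Tibble/data frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive), `strand`, `rank` (1..n in 5'->3' order of the mRNA).
#' @param genome Named character vector as returned by [read_genome()].
#' @return List with `cdna` (character) and `junctions` (integer vector of
#'   1-based cDNA positions of the last base of each upstream exon).
#' @export
build_cdna <- function(exons, genome) {
  exons <- dplyr::arrange(as_tibble(exons), .data$rank)
  if (nrow(exons) == 0L) stop("transcript has zero exons", call. = FALSE)
  chrom <- unique(exons$chrom); strand <- unique(exons$strand)
  if (length(chrom) != 1L || length(strand) != 1L) {
    stop("all exons must share one chromosome and one strand", call. = FALSE)
  }
  .check_strand(strand)
  if (!chrom %in% names(genome)) {
    stop("chromosome ", chrom, " absent from genome", call. = FALSE)
  }
  if (any(exons$start > exons$end) || any(exons$start < 1L) ||
      any(exons$end > nchar(genome[[chrom]]))) {
    stop("exon out of chromosome bounds on ", chrom, call. = FALSE)
  }
  pieces <- substring(genome[[chrom]], exons$start, exons$end)
  if (strand == "-") pieces <- vapply(pieces, revcomp, "", USE.NAMES = FALSE)
  lens <- exons$end - exons$start + 1L
  list(cdna = paste(pieces, collapse = ""),
       junctions = as.integer(utils::head(cumsum(lens), -1L)))
}

# junction table for one transcript: donor/acceptor are the genomic boundary
# coordinates of the upstream/downstream exon in transcription order
.transcript_junctions <- function(tr) {
  ex <- dplyr::arrange(tr$exons, .data$rank)
  n <- nrow(ex)
  if (n < 2L) {
    return(tibble(chrom = character(), donor = integer(),
                  acceptor = integer(), strand = character()))
  }
  up <- ex[-n, ]; down <- ex[-1L, ]
  if (ex$strand[1L] == "+") {
    tibble(chrom = up$chrom, donor = up$end, acceptor = down$start,
           strand = ex$strand[1L])
  } else {
    tibble(chrom = up$chrom, donor = up$start, acceptor = down$end,
           strand = ex$strand[1L])
  }
}

.junction_label <- function(chrom, donor, acceptor, strand) {
  paste0(chrom, ":", donor, "-", acceptor, "(", strand, ")")
}

#' Enumerate exon-exon junctions of a gene
#'
#' A junction is identified genomically by its (donor, acceptor, strand)
#' triple, so the same splice event shared by isoforms with different 5'
#' lengths unifies into one row.
#'
#' @param gene A `gene_model`.
#' @return Tibble with one row per distinct junction: `junction_id`, `chrom`,
#'   `donor`, `acceptor`, `strand`, list-column `transcript_ids` (the
#'   transcripts whose consecutive exon pair realises the junction) and
#'   `n_transcripts`. Rows ordered by donor then acceptor coordinate.
#' @export
enumerate_junctions <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  per_tr <- purrr::map_dfr(gene$transcripts, function(tr) {
    dplyr::mutate(.transcript_junctions(tr), transcript_id = tr$transcript_id)
  })
  if (nrow(per_tr) == 0L) {
    return(tibble(junction_id = character(), chrom = character(),
                  donor = integer(), acceptor = integer(), strand = character(),
                  transcript_ids = list(), n_transcripts = integer()))
  }
  per_tr |>
    dplyr::group_by(.data$chrom, .data$donor, .data$acceptor, .data$strand) |>
    dplyr::summarise(transcript_ids = list(sort(unique(.data$transcript_id))),
                     .groups = "drop") |>
    dplyr::arrange(.data$donor, .data$acceptor) |>
    dplyr::mutate(
      junction_id = .junction_label(.data$chrom, .data$donor, .data$acceptor, .data$strand),
      n_transcripts = lengths(.data$transcript_ids)
    ) |>
    dplyr::select("junction_id", "chrom", "donor", "acceptor", "strand",
                  "transcript_ids", "n_transcripts")
}

# cDNA position (1-based, last base of the upstream exon) of a genomic
# junction within one transcript, or NA if the transcript lacks it
.junction_cdna_pos <- function(tr, donor, acceptor) {
  jt <- .transcript_junctions(tr)
  k <- which(jt$donor == donor & jt$acceptor == acceptor)
  if (length(k) == 0L) return(NA_integer_)
  tr$junctions[k[1L]]
}

#' Load gene models from a GTF/GFF annotation plus genome FASTA
#'
#' Reads exon features, groups them into transcripts and genes, builds each
#' spliced cDNA, and flags the canonical transcript: the one carrying an
#' `Ensembl_canonical` tag if present, otherwise the transcript with the
#' longest cDNA (ties broken by lexicographically smallest transcript id).
#'
#' @param annotation Path to a GTF or GFF3 file with exon features carrying
#'   `gene_id` and `transcript_id` attributes.
#' @param genome Path to the genome FASTA, or a named vector from
#'   [read_genome()].
#' @return Named list of `gene_model` objects (one per `gene_id`).
#' @export
read_gene_models <- function(annotation, genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_genome(genome)
  }
  gr <- rtracklayer::import(annotation)
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0L) stop("annotation contains no exon features", call. = FALSE)
  mc <- S4Vectors::mcols(gr)
  tags <- if ("tag" %in% names(mc)) as.character(mc$tag) else rep(NA_character_, length(gr))
  ex <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(mc$gene_id),
    transcript_id = as.character(mc$transcript_id),
    gene_name = if ("gene_name" %in% names(mc)) as.character(mc$gene_name) else NA_character_,
    canonical_tag = !is.na(tags) & grepl("Ensembl_canonical", tags)
  )
  missing_chrom <- setdiff(unique(ex$chrom), names(genome))
  if (length(missing_chrom) > 0L) {
    off <- unique(ex$transcript_id[ex$chrom %in% missing_chrom])
    stop("annotation references chromosome(s) absent from the FASTA: ",
         paste(missing_chrom, collapse = ", "), " (transcript ",
         off[1L], ")", call. = FALSE)
  }
  genes <- split(ex, ex$gene_id)
  out <- lapply(genes, function(gx) {
    trs <- lapply(split(gx, gx$transcript_id), function(tx) {
      # rank by transcription order regardless of row order in the file
      tx <- dplyr::arrange(tx, .data$start)
      if (tx$strand[1L] == "-") tx <- tx[rev(seq_len(nrow(tx))), ]
      exons <- tibble(chrom = tx$chrom, start = tx$start, end = tx$end,
                      strand = tx$strand, rank = seq_len(nrow(tx)))
      sp <- build_cdna(exons, genome)
      new_transcript_model(tx$transcript_id[1L], tx$gene_id[1L], exons,
                           sp$cdna, sp$junctions,
                           is_canonical = any(tx$canonical_tag))
    })
    canon <- vapply(trs, function(t) t$is_canonical, logical(1))
    if (sum(canon) != 1L) {
      # fall back to longest cDNA, tie -> smallest transcript_id
      lens <- vapply(trs, function(t) nchar(t$cdna), integer(1))
      ids <- vapply(trs, `[[`, "", "transcript_id")
      pick <- ids[order(-lens, ids)][1L]
      trs <- lapply(trs, function(t) { t$is_canonical <- t$transcript_id == pick; t })
    }
    gname <- gx$gene_name[!is.na(gx$gene_name)]
    new_gene_model(gx$gene_id[1L],
                   if (length(gname) > 0L) gname[1L] else gx$gene_id[1L],
                   trs[order(names(trs))])
  })
  out
}

#' Parse a custom transcript from FASTA or GenBank
#'
#' FASTA input encodes junction placement in the header with a
#' `junctions=<comma-separated 0-based offsets>` token, each offset being the
#' 0-based cDNA position of the last base of an upstream exon. GenBank input
#' derives junctions from its exon feature boundaries. The returned
#' transcript is marked canonical and its `gene_id` equals the sequence id;
#' exon records are expressed in transcript coordinates on the `+` strand.
#'
#' @param file Path to a FASTA or GenBank flat file.
#' @param format `"auto"` (sniff), `"fasta"`, or `"genbank"`.
#' @return A `transcript_model`.
#' @export
parse_custom_transcript <- function(file, format = c("auto", "fasta", "genbank")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(file, n = 1L)
    format <- if (startsWith(first, ">")) "fasta" else "genbank"
  }
  if (format == "fasta") .parse_custom_fasta(file) else .parse_custom_genbank(file)
}

.custom_transcript_from_junctions <- function(id, seq, junctions_1based) {
  n <- nchar(seq)
  bounds <- c(0L, as.integer(junctions_1based), n)
  exons <- tibble(chrom = id,
                  start = utils::head(bounds, -1L) + 1L,
                  end = bounds[-1L],
                  strand = "+",
                  rank = seq_len(length(bounds) - 1L))
  new_transcript_model(id, gene_id = id, exons = exons, cdna = seq,
                       junctions = junctions_1based, is_canonical = TRUE)
}

.parse_custom_fasta <- function(file) {
  ss <- Biostrings::readDNAStringSet(file)
  if (length(ss) == 0L) stop("no sequence in FASTA", call. = FALSE)
  header <- names(ss)[1L]
  seq <- toupper(as.character(ss[[1L]]))
  .assert_dna(seq, allow_n = TRUE, what = "custom transcript")
  id <- sub("\\s.*$", "", header)
  m <- regmatches(header, regexpr("junctions=\\S+", header))
  if (length(m) == 0L) {
    warning("FASTA header has no 'junctions=' token; transcript treated as single-exon",
            call. = FALSE)
    return(.custom_transcript_from_junctions(id, seq, integer(0)))
  }
  raw <- strsplit(sub("^junctions=", "", m[1L]), ",", fixed = TRUE)[[1L]]
  offs <- suppressWarnings(as.numeric(trimws(raw)))
  if (any(is.na(offs)) || any(offs != floor(offs))) {
    stop("non-integer junction offset in FASTA header: ", m[1L], call. = FALSE)
  }
  # 0-based offset of the last base of an upstream exon; a valid junction
  # leaves at least one base downstream
  bad <- offs < 0 | offs > nchar(seq) - 2
  if (any(bad)) {
    stop("junction offset out of range for a ", nchar(seq), " nt sequence: ",
         offs[bad][1L], call. = FALSE)
  }
  .custom_transcript_from_junctions(id, seq, sort(as.integer(offs)) + 1L)
}

# Minimal GenBank flat-file reader: LOCUS id, exon feature locations, ORIGIN
# sequence. Only what a custom mRNA record needs.
.parse_custom_genbank <- function(file) {
  lines <- readLines(file)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus) > 0L) strsplit(trimws(sub("^LOCUS", "", locus[1L])), "\\s+")[[1L]][1L] else "custom"
  ex_lines <- grep("^\\s{5}exon\\s", lines, value = TRUE)
  locs <- regmatches(ex_lines, regexpr("[0-9]+\\.\\.[0-9]+", ex_lines))
  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0L) stop("GenBank record has no ORIGIN block", call. = FALSE)
  seq_lines <- lines[(origin_at[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  .assert_dna(seq, allow_n = TRUE, what = "GenBank sequence")
  if (length(locs) == 0L) {
    warning("GenBank record has no exon features; transcript treated as single-exon",
            call. = FALSE)
    return(.custom_transcript_from_junctions(id, seq, integer(0)))
  }
  se <- do.call(rbind, lapply(strsplit(locs, "..", fixed = TRUE), as.integer))
  se <- se[order(se[, 1L]), , drop = FALSE]
  if (any(se[, 2L] > nchar(seq))) stop("exon feature beyond sequence end", call. = FALSE)
  lens <- se[, 2L] - se[, 1L] + 1L
  .custom_transcript_from_junctions(id, seq, utils::head(cumsum(lens), -1L))
}

#' Wrap a custom transcript as a single-transcript gene model
#'
#' @param transcript A `transcript_model`, e.g. from [parse_custom_transcript()].
#' @return A `gene_model` containing only that transcript (canonical).
#' @export
as_gene_model <- function(transcript) {
  stopifnot(inherits(transcript, "transcript_model"))
  transcript$is_canonical <- TRUE
  new_gene_model(transcript$gene_id, transcript$gene_id, list(transcript))
}
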