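# Common-variant masking: positions whose allele frequency reaches the
# threshold are hard-masked to 'N' in the design template so no primer can
# overlap them.

#' Load common variants from a VCF into a position mask
#'
#' A record contributes every reference position it spans (so an indel masks
#' its full REF footprint) when its allele frequency reaches `threshold`.
#' Multi-allelic records use the maximum alternate-allele frequency.
#'
#' @param vcf Path to a VCF 4.x file.
#' @param threshold Allele-frequency threshold as a fraction; positions with
#'   frequency >= `threshold` are masked (default 0.01, i.e. the common-variant
#'   1% convention).
#' @param af_key INFO key holding the allele frequency (default `"AF"`).
#' @return A `variant_mask`: list with `positions` (tibble `chrom`, `pos`,
#'   1-based), `threshold`, `af_key`, and `n_skipped` (records lacking the
#'   frequency field, skipped with a warning).
#' @export
load_common_variants <- function(vcf, threshold = 0.01, af_key = "AF") {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be a fraction in (0, 1]", call. = FALSE)
  }
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix) # single-record VCFs drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  n_skipped <- 0L
  rows <- list()
  if (nrow(fix) > 0L) {
    info <- vcfR::extract.info(v, element = af_key)
    for (i in seq_len(nrow(fix))) {
      raw <- info[i]
      if (is.na(raw) || !nzchar(raw)) {
        n_skipped <- n_skipped + 1L
        next
      }
      af <- suppressWarnings(as.numeric(strsplit(raw, ",", fixed = TRUE)[[1L]]))
      if (all(is.na(af))) {
        n_skipped <- n_skipped + 1L
        next
      }
      if (max(af, na.rm = TRUE) >= threshold) {
        pos <- as.integer(fix$POS[i])
        ref_len <- nchar(fix$REF[i])
        rows[[length(rows) + 1L]] <- tibble(chrom = fix$CHROM[i],
                                            pos = pos:(pos + ref_len - 1L))
      }
    }
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " VCF record(s) lacked INFO/", af_key,
            " and were skipped", call. = FALSE)
  }
  positions <- if (length(rows) > 0L) {
    dplyr::distinct(dplyr::arrange(dplyr::bind_rows(rows), .data$chrom, .data$pos))
  } else {
    tibble(chrom = character(), pos = integer())
  }
  structure(list(positions = positions, threshold = threshold,
                 af_key = af_key, n_skipped = n_skipped),
            class = "variant_mask")
}

#' An empty variant mask (masking disabled)
#'
#' @param threshold Threshold recorded on the mask (unused; default 0.01).
#' @return A `variant_mask` masking nothing, so designs are identical to
#'   running without any mask.
#' @export
empty_variant_mask <- function(threshold = 0.01) {
  structure(list(positions = tibble(chrom = character(), pos = integer()),
                 threshold = threshold, af_key = "AF", n_skipped = 0L),
            class = "variant_mask")
}

#' @export
print.variant_mask <- function(x, ...) {
  cat("<variant_mask> ", nrow(x$positions), " masked position(s), threshold ",
      x$threshold, "\n", sep = "")
  invisible(x)
}

# project genomic positions of one transcript into cDNA coordinates;
# returns a tibble (genomic pos, cdna pos), both 1-based
.genomic_to_cdna <- function(transcript) {
  ex <- dplyr::arrange(transcript$exons, .data$rank)
  offset <- 0L
  out <- vector("list", nrow(ex))
  for (k in seq_len(nrow(ex))) {
    gpos <- ex$start[k]:ex$end[k]
    # exon sequence appears reversed in the cDNA on the minus strand
    if (ex$strand[k] == "-") gpos <- rev(gpos)
    out[[k]] <- tibble(chrom = ex$chrom[k], genomic = gpos,
                       cdna = offset + seq_along(gpos))
    offset <- offset + length(gpos)
  }
  dplyr::bind_rows(out)
}

#' Mask a transcript's cDNA at common-variant positions
#'
#' Genomic masked positions are projected through the exon structure into
#' cDNA coordinates; intronic variants therefore never change the template.
#' Masked bases become `'N'`; length is preserved.
#'
#' @param transcript A `transcript_model`.
#' @param mask A `variant_mask` from [load_common_variants()] (or
#'   [empty_variant_mask()]).
#' @return The cDNA string with masked positions replaced by `'N'`.
#' @export
apply_mask <- function(transcript, mask) {
  stopifnot(inherits(transcript, "transcript_model"),
            inherits(mask, "variant_mask"))
  cdna <- transcript$cdna
  if (nrow(mask$positions) == 0L) return(cdna)
  proj <- .genomic_to_cdna(transcript)
  hit <- dplyr::inner_join(proj, mask$positions,
                           by = c(chrom = "chrom", genomic = "pos"))
  if (nrow(hit) == 0L) return(cdna)
  chars <- .str_chars(cdna)
  chars[hit$cdna] <- "N"
  paste(chars, collapse = "")
}
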