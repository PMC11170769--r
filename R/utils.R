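# Internal sequence helpers. Sequences are plain uppercase character strings
# over {A,C,G,T,N}; Biostrings does the heavy lifting where it matters.

.valid_dna <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  is.character(x) && length(x) == 1L && !is.na(x) && grepl(pat, x)
}

.assert_dna <- function(x, allow_n = TRUE, what = "sequence") {
  if (!.valid_dna(x, allow_n = allow_n)) {
    stop(what, " must be an uppercase DNA string over {A,C,G,T",
         if (allow_n) ",N", "}", call. = FALSE)
  }
  invisible(x)
}

revcomp <- function(x) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", x))))
}

# Vectorised single-character complement (N -> N)
.comp_chars <- function(chars) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[chars])
}

.str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

.check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
  invisible(strand)
}
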