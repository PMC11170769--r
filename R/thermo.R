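# Oligo thermodynamics: nearest-neighbor melting temperature, GC content and
# ungapped complementarity (dimer / hairpin) scoring.

# Unified nearest-neighbor parameters (Allawi & SantaLucia), kcal/mol and
# cal/(mol*K). Dinucleotides absent from the published table take the values
# of their reverse complement (duplex symmetry). Stored as integers times 10
# so enthalpy/entropy sums are exact and independent of summation order: any
# two code paths (per-oligo summation, template prefix sums) then yield
# bit-identical melting temperatures.
.NN_DH10 <- c(AA = -79L, AT = -72L, TA = -72L, CA = -85L, GT = -84L,
              CT = -78L, GA = -82L, CG = -106L, GC = -98L, GG = -80L,
              TT = -79L, TG = -85L, AC = -84L, AG = -78L, TC = -82L, CC = -80L)
.NN_DS10 <- c(AA = -222L, AT = -204L, TA = -213L, CA = -227L, GT = -224L,
              CT = -210L, GA = -222L, CG = -272L, GC = -244L, GG = -199L,
              TT = -222L, TG = -227L, AC = -224L, AG = -210L, TC = -222L,
              CC = -199L)
# Duplex initiation at each terminal base pair
.NN_INIT_DH10 <- c(A = 23L, T = 23L, G = 1L, C = 1L)
.NN_INIT_DS10 <- c(A = 41L, T = 41L, G = -28L, C = -28L)
.GAS_R <- 1.987 # cal/(mol*K)

# Tm in Celsius from 10x-scaled integer enthalpy/entropy sums
.tm_from_sums <- function(dh10, ds10, n, monovalent_mM, oligo_nM, selfcomp = FALSE) {
  ds <- ds10 / 10
  if (any(selfcomp)) ds <- ds - 1.4 * selfcomp
  ds_salt <- 0.368 * (n - 1L) * log(monovalent_mM / 1000)
  conc <- ifelse(selfcomp, oligo_nM * 1e-9, oligo_nM * 1e-9 / 4)
  unname(1000 * (dh10 / 10) / (ds + ds_salt + .GAS_R * log(conc)) - 273.15)
}

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature of a primer against its perfect complement,
#' computed by nearest-neighbor enthalpy/entropy summation with the unified
#' parameter set, terminal initiation terms, a monovalent-salt entropy
#' correction of `0.368 * (N - 1) * ln([Na+])`, and the standard
#' concentration term (`CT/4` for a non-self-complementary duplex, `CT` for
#' a self-complementary one).
#'
#' @param seq Primer sequence, 5'->3', uppercase over \{A,C,G,T\}; length >= 2.
#'   Ambiguous bases (including `N`) are rejected because the thermodynamic
#'   table is defined over the four unambiguous bases only.
#' @param monovalent_mM Monovalent cation concentration in mM (default 50).
#' @param oligo_nM Total oligonucleotide concentration in nM (default 500).
#' @return Melting temperature in degrees Celsius (deterministic).
#' @examples
#' melting_temperature("ATGCATGCATGCATGCATGC")
#' @export
melting_temperature <- function(seq, monovalent_mM = 50, oligo_nM = 500) {
  .assert_dna(seq, allow_n = FALSE, what = "primer")
  n <- nchar(seq)
  if (n < 2L) stop("sequence must be at least 2 nt for the NN model", call. = FALSE)
  chars <- .str_chars(seq)
  dinucs <- paste0(chars[-n], chars[-1L])
  dh10 <- sum(.NN_DH10[dinucs]) + .NN_INIT_DH10[chars[1L]] + .NN_INIT_DH10[chars[n]]
  ds10 <- sum(.NN_DS10[dinucs]) + .NN_INIT_DS10[chars[1L]] + .NN_INIT_DS10[chars[n]]
  selfcomp <- identical(seq, revcomp(seq))
  .tm_from_sums(dh10, ds10, n, monovalent_mM, oligo_nM, selfcomp)
}

#' GC fraction of a sequence
#'
#' @param seq Non-empty DNA string.
#' @return `(#G + #C) / length` as a fraction in \[0, 1\].
#' @examples
#' gc_fraction("GGCC")
#' @export
gc_fraction <- function(seq) {
  .assert_dna(seq, allow_n = TRUE, what = "sequence")
  if (nchar(seq) == 0L) stop("sequence must be non-empty", call. = FALSE)
  chars <- .str_chars(seq)
  sum(chars %in% c("G", "C")) / length(chars)
}

# match = +1, mismatch = -1 over the overlap of a (5'->3') against b read
# 3'->5' (antiparallel), at a fixed relative offset.
.duplex_frame_score <- function(a_chars, b_comp_rev, d) {
  n <- length(a_chars); m <- length(b_comp_rev)
  i <- max(1L, d + 1L):min(n, d + m)
  sum(ifelse(a_chars[i] == b_comp_rev[i - d], 1L, -1L))
}

#' Ungapped complementarity score between two oligos
#'
#' Scores every ungapped antiparallel alignment of `a` against `b`
#' (match +1, mismatch -1 over the overlapping window) and returns the best
#' alignment score, floored at zero. With `anchor_3p = TRUE` only alignments
#' that include the 3'-terminal base of `a` are considered, which is the
#' score relevant to extension artefacts. The plain score is symmetric:
#' `interaction_score(a, b) == interaction_score(b, a)`.
#'
#' @param a,b Oligo sequences 5'->3' over \{A,C,G,T\}. `b` defaults to `a`
#'   (homodimer).
#' @param anchor_3p Restrict to alignments covering the 3' terminus of `a`.
#' @return Non-negative integer score; `nchar(a)` for a perfect duplex.
#' @examples
#' interaction_score("ACGTACGT", revcomp("ACGTACGT")) # 8
#' @export
interaction_score <- function(a, b = a, anchor_3p = FALSE) {
  .assert_dna(a, allow_n = FALSE, what = "oligo a")
  .assert_dna(b, allow_n = FALSE, what = "oligo b")
  if (nchar(a) == 0L || nchar(b) == 0L) stop("oligos must be non-empty", call. = FALSE)
  a_chars <- .str_chars(a)
  n <- length(a_chars)
  # reverse b, then complement: a[i] matching this vector means a[i] pairs b[j]
  b_comp_rev <- .comp_chars(rev(.str_chars(b)))
  m <- length(b_comp_rev)
  offsets <- (-(m - 1L)):(n - 1L)
  if (anchor_3p) offsets <- offsets[offsets + m >= n]
  best <- 0L
  for (d in offsets) best <- max(best, .duplex_frame_score(a_chars, b_comp_rev, d))
  best
}

#' Hairpin self-complementarity score
#'
#' Best ungapped stem score of a sequence folding back on itself, requiring a
#' loop of at least `min_loop` unpaired bases between the stem halves
#' (match +1, mismatch -1 within a contiguous stem), floored at zero.
#'
#' @param seq Oligo 5'->3' over \{A,C,G,T\}.
#' @param min_loop Minimum unpaired loop length (default 3 nt).
#' @return Non-negative integer stem score.
#' @export
hairpin_score <- function(seq, min_loop = 3L) {
  .assert_dna(seq, allow_n = FALSE, what = "oligo")
  chars <- .str_chars(seq)
  comp <- .comp_chars(chars)
  n <- length(chars)
  best <- 0L
  # base i pairs base j (i < j) when chars[i] complements chars[j] and
  # j - i - 1 >= min_loop; a stem is a run of consecutive pairs within a
  # fixed frame c = i + j.
  for (cc in seq_len(2L * n - 1L)) {
    i <- seq_len(n)
    j <- cc - i
    ok <- j > i & j <= n & (j - i - 1L) >= min_loop
    if (!any(ok)) next
    s <- ifelse(chars[i[ok]] == comp[j[ok]], 1L, -1L)
    run <- 0L
    for (v in s) { # max contiguous-subarray sum
      run <- max(v, run + v)
      best <- max(best, run)
    }
  }
  best
}
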