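# Primer pair enumeration anchored on (or flanking) an exon-exon junction.
#
# Template coordinates are 1-based cDNA positions; a junction at position j
# sits between template bases j and j+1. A forward primer occupies template
# [start, end] and reads the template strand 5'->3'; a reverse primer
# occupies [start, end] but is the reverse complement, so its 3' terminus
# lies at template position `start`.

#' Primer design parameters
#'
#' @param primer_len Length `c(min, opt, max)` in nt.
#' @param tm Melting temperature window `c(min, opt, max)` in degrees C.
#' @param gc GC-content window `c(min, max)` as fractions.
#' @param min_amplicon,max_amplicon Amplicon length bounds in nt (qPCR-sized
#'   products by default).
#' @param junction_overlap_3p,junction_overlap_5p Minimum number of bases a
#'   junction-spanning primer must extend past the junction on its 3' and 5'
#'   sides.
#' @param mode `"span"` (one primer crosses the junction) or `"flank"`
#'   (primers on opposite sides, amplicon crosses it).
#' @param max_pair_tm_diff Maximum |Tm(forward) - Tm(reverse)| in degrees C.
#' @param dimer_any_limit Reject a primer/pair when any ungapped
#'   complementarity score (hairpin, homodimer, heterodimer) reaches this.
#' @param dimer_3p_limit Reject a pair when the 3'-anchored heterodimer score
#'   reaches this.
#' @param monovalent_mM,oligo_nM Salt and total oligo concentration for the
#'   nearest-neighbor Tm model.
#' @param max_candidates Maximum pairs returned per junction (best penalty
#'   first).
#' @param w_len,w_gc Penalty weights: degrees-C-equivalent per nt of length
#'   deviation from the optimum and per unit of GC-fraction deviation from
#'   the window midpoint.
#' @return A validated `design_params` list.
#' @export
design_params <- function(primer_len = c(18L, 20L, 25L),
                          tm = c(59, 60, 62),
                          gc = c(0.35, 0.65),
                          min_amplicon = 70L,
                          max_amplicon = 200L,
                          junction_overlap_3p = 4L,
                          junction_overlap_5p = 4L,
                          mode = c("span", "flank"),
                          max_pair_tm_diff = 2,
                          dimer_any_limit = 8L,
                          dimer_3p_limit = 5L,
                          monovalent_mM = 50,
                          oligo_nM = 500,
                          max_candidates = 50L,
                          w_len = 0.25,
                          w_gc = 5) {
  mode <- match.arg(mode)
  stopifnot(length(primer_len) == 3L, length(tm) == 3L, length(gc) == 2L)
  if (!(primer_len[1] <= primer_len[2] && primer_len[2] <= primer_len[3])) {
    stop("primer_len must satisfy min <= opt <= max", call. = FALSE)
  }
  if (!(tm[1] <= tm[2] && tm[2] <= tm[3])) {
    stop("tm must satisfy min <= opt <= max", call. = FALSE)
  }
  if (gc[1] > gc[2] || gc[1] < 0 || gc[2] > 1) {
    stop("gc must be an increasing pair of fractions", call. = FALSE)
  }
  if (min_amplicon <= 2L * primer_len[1]) {
    stop("min_amplicon must exceed twice the minimum primer length", call. = FALSE)
  }
  if (max_amplicon < min_amplicon) stop("max_amplicon < min_amplicon", call. = FALSE)
  structure(
    list(primer_len = as.integer(primer_len), tm = as.numeric(tm),
         gc = as.numeric(gc), min_amplicon = as.integer(min_amplicon),
         max_amplicon = as.integer(max_amplicon),
         junction_overlap_3p = as.integer(junction_overlap_3p),
         junction_overlap_5p = as.integer(junction_overlap_5p),
         mode = mode, max_pair_tm_diff = as.numeric(max_pair_tm_diff),
         dimer_any_limit = as.integer(dimer_any_limit),
         dimer_3p_limit = as.integer(dimer_3p_limit),
         monovalent_mM = monovalent_mM, oligo_nM = oligo_nM,
         max_candidates = as.integer(max_candidates),
         w_len = w_len, w_gc = w_gc),
    class = "design_params"
  )
}

.new_rejections <- function() {
  setNames(integer(9L),
           c("masked", "tm", "gc", "hairpin", "homodimer",
             "amplicon_length", "tm_diff", "heterodimer", "heterodimer_3p"))
}

# Prefix-sum tables over the template so whole window sets are screened
# vectorised. The NN model is duplex-symmetric (Tm(s) == Tm(revcomp(s))), so
# window thermodynamics are computed on the template strand regardless of
# primer role.
.template_profile <- function(template, params) {
  chars <- .str_chars(template)
  n <- length(chars)
  is_n <- chars == "N"
  din <- paste0(chars[-n], chars[-1L])
  dh10 <- .NN_DH10[din]; ds10 <- .NN_DS10[din]
  dh10[is.na(dh10)] <- 0L; ds10[is.na(ds10)] <- 0L # N windows are dropped anyway
  list(
    chars = chars, n = n,
    cum_n = cumsum(is_n),
    cum_gc = cumsum(chars %in% c("G", "C")),
    cum_dh10 = cumsum(dh10),
    cum_ds10 = cumsum(ds10)
  )
}

# Build and screen single-primer candidates for a set of (start, end) windows.
# Returns list(candidates = tibble, rejections = named counts).
.screen_candidates <- function(template, starts, ends, role, params,
                               profile = NULL) {
  rej <- .new_rejections()
  if (is.null(profile)) profile <- .template_profile(template, params)
  n <- profile$n
  ok <- starts >= 1L & ends <= n
  starts <- starts[ok]; ends <- ends[ok]
  empty <- tibble(role = character(), start = integer(), end = integer(),
                  len = integer(), seq = character(), tm = numeric(),
                  gc = numeric())
  if (length(starts) == 0L) return(list(candidates = empty, rejections = rej))

  # prefix-sum difference; guard from == 1 (index 0 would drop elements and
  # misalign the vectors)
  csum <- function(cum, from, to) {
    base <- cum[pmax(from - 1L, 1L)]
    base[from == 1L] <- 0
    unname(cum[to] - base)
  }
  masked <- csum(profile$cum_n, starts, ends) > 0L
  rej[["masked"]] <- sum(masked)
  starts <- starts[!masked]; ends <- ends[!masked]
  if (length(starts) == 0L) return(list(candidates = empty, rejections = rej))

  lens <- ends - starts + 1L
  dh10 <- csum(profile$cum_dh10, starts, ends - 1L) +
    .NN_INIT_DH10[profile$chars[starts]] + .NN_INIT_DH10[profile$chars[ends]]
  ds10 <- csum(profile$cum_ds10, starts, ends - 1L) +
    .NN_INIT_DS10[profile$chars[starts]] + .NN_INIT_DS10[profile$chars[ends]]
  raw <- substring(template, starts, ends)
  # self-complementary windows take the symmetry correction; they are rare
  # (a palindromic primer is its own perfect homodimer and dies later anyway)
  pal <- lens %% 2L == 0L & vapply(raw, function(s) identical(s, revcomp(s)),
                                   logical(1), USE.NAMES = FALSE)
  tm <- .tm_from_sums(dh10, ds10, lens, params$monovalent_mM, params$oligo_nM,
                      selfcomp = pal)
  bad_tm <- tm < params$tm[1] | tm > params$tm[3]
  rej[["tm"]] <- sum(bad_tm)
  gc <- csum(profile$cum_gc, starts, ends) / lens
  bad_gc <- !bad_tm & (gc < params$gc[1] | gc > params$gc[2])
  rej[["gc"]] <- sum(bad_gc)
  keep <- !bad_tm & !bad_gc
  starts <- starts[keep]; ends <- ends[keep]; lens <- lens[keep]
  tm <- tm[keep]; gc <- gc[keep]; raw <- raw[keep]
  if (length(starts) == 0L) return(list(candidates = empty, rejections = rej))

  seqs <- if (role == "reverse") vapply(raw, revcomp, "", USE.NAMES = FALSE) else raw
  hp <- vapply(seqs, hairpin_score, integer(1), USE.NAMES = FALSE)
  bad_hp <- hp >= params$dimer_any_limit
  rej[["hairpin"]] <- sum(bad_hp)
  hd <- rep(0L, length(seqs))
  hd[!bad_hp] <- vapply(seqs[!bad_hp], function(s) interaction_score(s, s),
                        integer(1), USE.NAMES = FALSE)
  bad_hd <- !bad_hp & hd >= params$dimer_any_limit
  rej[["homodimer"]] <- sum(bad_hd)
  keep <- !bad_hp & !bad_hd
  cands <- tibble(role = role, start = starts[keep], end = ends[keep],
                  len = lens[keep], seq = seqs[keep], tm = unname(tm[keep]),
                  gc = gc[keep])
  list(candidates = cands, rejections = rej)
}

# enumeration windows -------------------------------------------------------

# forward primers whose body crosses the junction with the required overhangs
.span_forward_windows <- function(j, params) {
  lens <- params$primer_len[1]:params$primer_len[3]
  ov3 <- params$junction_overlap_3p; ov5 <- params$junction_overlap_5p
  out <- list()
  for (L in lens) {
    e_lo <- j + ov3             # 3'-side overlap = e - j >= ov3
    e_hi <- j + L - ov5         # 5'-side overlap = j - s + 1 >= ov5
    if (e_hi < e_lo) next
    e <- e_lo:e_hi
    out[[length(out) + 1L]] <- tibble(start = e - L + 1L, end = e)
  }
  dplyr::bind_rows(out)
}

# reverse primers whose body crosses the junction (3' terminus at `start`)
.span_reverse_windows <- function(j, params) {
  lens <- params$primer_len[1]:params$primer_len[3]
  ov3 <- params$junction_overlap_3p; ov5 <- params$junction_overlap_5p
  out <- list()
  for (L in lens) {
    s_hi <- j - ov3 + 1L        # 3'-side overlap = j - s + 1 >= ov3
    s_lo <- j - L + ov5 + 1L    # 5'-side overlap = e - j >= ov5
    if (s_hi < s_lo) next
    s <- s_lo:s_hi
    out[[length(out) + 1L]] <- tibble(start = s, end = s + L - 1L)
  }
  dplyr::bind_rows(out)
}

# primers fully on one side of the junction, within amplicon reach
.side_windows <- function(j, side, params, n) {
  lens <- params$primer_len[1]:params$primer_len[3]
  out <- list()
  for (L in lens) {
    if (side == "upstream") {
      e_lo <- max(L, j - params$max_amplicon + L + 1L)
      if (e_lo > j) next
      e <- e_lo:j
      out[[length(out) + 1L]] <- tibble(start = e - L + 1L, end = e)
    } else {
      s_hi <- min(n - L + 1L, j + params$max_amplicon - L)
      if (s_hi < j + 1L) next
      s <- (j + 1L):s_hi
      out[[length(out) + 1L]] <- tibble(start = s, end = s + L - 1L)
    }
  }
  dplyr::bind_rows(out)
}

.pair_penalty <- function(fwd, rev, params) {
  gc_opt <- mean(params$gc)
  abs(fwd$tm - params$tm[2]) + abs(rev$tm - params$tm[2]) +
    abs(fwd$tm - rev$tm) +
    params$w_len * (abs(fwd$len - params$primer_len[2]) +
                    abs(rev$len - params$primer_len[2])) +
    params$w_gc * (abs(fwd$gc - gc_opt) + abs(rev$gc - gc_opt))
}

# cross all forwards with all reverses, apply pair-level constraints in
# increasing cost order, counting the first failing cause per pair
.pair_up <- function(fwds, revs, params, rej) {
  if (nrow(fwds) == 0L || nrow(revs) == 0L) return(list(pairs = NULL, rejections = rej))
  grid <- tidyr::expand_grid(f = seq_len(nrow(fwds)), r = seq_len(nrow(revs)))
  amp_len <- revs$end[grid$r] - fwds$start[grid$f] + 1L
  bad_len <- amp_len < params$min_amplicon | amp_len > params$max_amplicon
  rej[["amplicon_length"]] <- rej[["amplicon_length"]] + sum(bad_len)
  grid <- grid[!bad_len, ]; amp_len <- amp_len[!bad_len]
  if (nrow(grid) == 0L) return(list(pairs = NULL, rejections = rej))
  tm_diff <- abs(fwds$tm[grid$f] - revs$tm[grid$r])
  bad_tm <- tm_diff > params$max_pair_tm_diff
  rej[["tm_diff"]] <- rej[["tm_diff"]] + sum(bad_tm)
  grid <- grid[!bad_tm, ]; amp_len <- amp_len[!bad_tm]
  if (nrow(grid) == 0L) return(list(pairs = NULL, rejections = rej))
  # dimer screening is the expensive step: walk the grid in final output
  # order (penalty, then the deterministic tie-breaks) and stop once
  # max_candidates pairs are accepted — any unevaluated pair ranks below the
  # ones already accepted, so the emitted set is unaffected
  penalty <- .pair_penalty(fwds[grid$f, ], revs[grid$r, ], params)
  ord <- order(penalty, amp_len, fwds$start[grid$f], fwds$len[grid$f],
               revs$start[grid$r], revs$len[grid$r])
  grid <- grid[ord, ]; amp_len <- amp_len[ord]; penalty <- penalty[ord]
  keep <- logical(nrow(grid))
  het <- integer(nrow(grid)); het3 <- integer(nrow(grid))
  n_accepted <- 0L
  for (i in seq_len(nrow(grid))) {
    if (n_accepted >= params$max_candidates) break
    fs <- fwds$seq[grid$f[i]]; rs <- revs$seq[grid$r[i]]
    h <- interaction_score(fs, rs)
    if (h >= params$dimer_any_limit) {
      rej[["heterodimer"]] <- rej[["heterodimer"]] + 1L; next
    }
    h3 <- max(interaction_score(fs, rs, anchor_3p = TRUE),
              interaction_score(rs, fs, anchor_3p = TRUE))
    if (h3 >= params$dimer_3p_limit) {
      rej[["heterodimer_3p"]] <- rej[["heterodimer_3p"]] + 1L; next
    }
    keep[i] <- TRUE; het[i] <- h; het3[i] <- h3
    n_accepted <- n_accepted + 1L
  }
  grid <- grid[keep, ]; amp_len <- amp_len[keep]
  het <- het[keep]; het3 <- het3[keep]
  if (nrow(grid) == 0L) return(list(pairs = NULL, rejections = rej))
  f <- fwds[grid$f, ]; r <- revs[grid$r, ]
  pairs <- tibble(
    fwd_seq = f$seq, rev_seq = r$seq,
    fwd_start = f$start, fwd_end = f$end, fwd_len = f$len,
    rev_start = r$start, rev_end = r$end, rev_len = r$len,
    fwd_tm = f$tm, rev_tm = r$tm, fwd_gc = f$gc, rev_gc = r$gc,
    amplicon_start = f$start, amplicon_end = r$end,
    amplicon_len = as.integer(amp_len),
    heterodimer = het, heterodimer_3p = het3,
    pair_penalty = .pair_penalty(f, r, params)
  )
  list(pairs = pairs, rejections = rej)
}

#' Enumerate junction-anchored primer pairs
#'
#' Exhaustively enumerates primer windows around one junction of a (masked)
#' cDNA template, screens each primer against length, mask, Tm, GC, hairpin
#' and homodimer constraints, then pairs primers across the junction subject
#' to amplicon-length, Tm-difference and heterodimer constraints. In `span`
#' mode exactly one primer of each pair crosses the junction with at least
#' the configured 3'/5' overhangs; in `flank` mode both primers sit strictly
#' on opposite sides and only the amplicon crosses it. Enumeration is
#' deterministic; no randomness is involved.
#'
#' @param template cDNA template string (possibly containing `'N'` at masked
#'   positions, which no primer may cover).
#' @param junction_pos 1-based template position of the last base of the
#'   upstream exon.
#' @param params A [design_params()] object.
#' @return Tibble of pairs, best `pair_penalty` first (ties: amplicon length,
#'   then coordinates), at most `params$max_candidates` rows, with columns for
#'   sequences, coordinates, Tm, GC, dimer scores, junction overlaps and
#'   `spans` (`"forward"`, `"reverse"` or `"none"`). The attribute
#'   `"rejections"` carries a named histogram of every rejection cause.
#' @export
generate_pairs <- function(template, junction_pos, params = design_params()) {
  .assert_dna(template, allow_n = TRUE, what = "template")
  stopifnot(inherits(params, "design_params"))
  n <- nchar(template)
  j <- as.integer(junction_pos)
  if (j < 1L || j >= n) stop("junction_pos out of template range", call. = FALSE)
  if (n < params$min_amplicon) stop("template shorter than min_amplicon", call. = FALSE)
  rej <- .new_rejections()
  all_pairs <- list()
  profile <- .template_profile(template, params)

  if (params$mode == "span") {
    w <- .span_forward_windows(j, params)
    sf <- .screen_candidates(template, w$start, w$end, "forward", params, profile)
    rej <- rej + sf$rejections
    dn <- .side_windows(j, "downstream", params, n)
    dr <- .screen_candidates(template, dn$start, dn$end, "reverse", params, profile)
    rej <- rej + dr$rejections
    p1 <- .pair_up(sf$candidates, dr$candidates, params, rej)
    rej <- p1$rejections
    if (!is.null(p1$pairs)) {
      all_pairs[[1L]] <- dplyr::mutate(p1$pairs, spans = "forward")
    }
    w2 <- .span_reverse_windows(j, params)
    sr <- .screen_candidates(template, w2$start, w2$end, "reverse", params, profile)
    rej <- rej + sr$rejections
    up <- .side_windows(j, "upstream", params, n)
    uf <- .screen_candidates(template, up$start, up$end, "forward", params, profile)
    rej <- rej + uf$rejections
    p2 <- .pair_up(uf$candidates, sr$candidates, params, rej)
    rej <- p2$rejections
    if (!is.null(p2$pairs)) {
      all_pairs[[2L]] <- dplyr::mutate(p2$pairs, spans = "reverse")
    }
  } else {
    up <- .side_windows(j, "upstream", params, n)
    uf <- .screen_candidates(template, up$start, up$end, "forward", params, profile)
    rej <- rej + uf$rejections
    dn <- .side_windows(j, "downstream", params, n)
    dr <- .screen_candidates(template, dn$start, dn$end, "reverse", params, profile)
    rej <- rej + dr$rejections
    p <- .pair_up(uf$candidates, dr$candidates, params, rej)
    rej <- p$rejections
    if (!is.null(p$pairs)) all_pairs[[1L]] <- dplyr::mutate(p$pairs, spans = "none")
  }

  out <- if (length(all_pairs) > 0L) dplyr::bind_rows(all_pairs) else
    tibble(fwd_seq = character(), rev_seq = character(),
           fwd_start = integer(), fwd_end = integer(), fwd_len = integer(),
           rev_start = integer(), rev_end = integer(), rev_len = integer(),
           fwd_tm = numeric(), rev_tm = numeric(),
           fwd_gc = numeric(), rev_gc = numeric(),
           amplicon_start = integer(), amplicon_end = integer(),
           amplicon_len = integer(), heterodimer = integer(),
           heterodimer_3p = integer(), pair_penalty = numeric(),
           spans = character())
  out <- dplyr::mutate(
    out,
    junction_pos = j,
    overlap_5p = dplyr::case_when(
      .data$spans == "forward" ~ j - .data$fwd_start + 1L,
      .data$spans == "reverse" ~ .data$rev_end - j,
      TRUE ~ 0L
    ),
    overlap_3p = dplyr::case_when(
      .data$spans == "forward" ~ .data$fwd_end - j,
      .data$spans == "reverse" ~ j - .data$rev_start + 1L,
      TRUE ~ 0L
    )
  )
  out <- dplyr::arrange(out, .data$pair_penalty, .data$amplicon_len,
                        .data$fwd_start, .data$fwd_len, .data$rev_start,
                        .data$rev_len)
  out <- utils::head(out, params$max_candidates)
  attr(out, "rejections") <- rej
  out
}

#' Rejection histogram of a [generate_pairs()] result
#'
#' @param pairs Tibble returned by [generate_pairs()].
#' @return Tibble with `cause` and `n`, one row per rejection cause observed.
#' @export
rejection_summary <- function(pairs) {
  rej <- attr(pairs, "rejections")
  if (is.null(rej)) rej <- .new_rejections()
  tibble(cause = names(rej), n = as.integer(rej)) |>
    dplyr::filter(.data$n > 0L) |>
    dplyr::arrange(dplyr::desc(.data$n))
}

#' Independently re-validate emitted primer pairs
#'
#' Re-checks every constraint [generate_pairs()] promises, directly from the
#' template and parameters: window bounds, mask exclusion, Tm/GC windows,
#' dimer limits, amplicon geometry and the junction-anchor (or flanking)
#' rule. Used by the test-suite as an independent validator; exported so
#' users can audit designs.
#'
#' @param pairs Tibble from [generate_pairs()].
#' @param template,junction_pos,params The inputs the pairs were designed on.
#' @return Logical vector, one entry per pair: `TRUE` iff every constraint
#'   holds.
#' @export
validate_pairs <- function(pairs, template, junction_pos, params = design_params()) {
  j <- as.integer(junction_pos)
  vapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    fwd_tmpl <- substr(template, p$fwd_start, p$fwd_end)
    rev_tmpl <- substr(template, p$rev_start, p$rev_end)
    ok <- !grepl("N", fwd_tmpl, fixed = TRUE) &&
      !grepl("N", rev_tmpl, fixed = TRUE) &&
      identical(p$fwd_seq, fwd_tmpl) &&
      identical(p$rev_seq, revcomp(rev_tmpl)) &&
      p$fwd_len >= params$primer_len[1] && p$fwd_len <= params$primer_len[3] &&
      p$rev_len >= params$primer_len[1] && p$rev_len <= params$primer_len[3] &&
      p$fwd_tm >= params$tm[1] && p$fwd_tm <= params$tm[3] &&
      p$rev_tm >= params$tm[1] && p$rev_tm <= params$tm[3] &&
      abs(p$fwd_tm - p$rev_tm) <= params$max_pair_tm_diff &&
      p$fwd_gc >= params$gc[1] && p$fwd_gc <= params$gc[2] &&
      p$rev_gc >= params$gc[1] && p$rev_gc <= params$gc[2] &&
      p$amplicon_len == p$rev_end - p$fwd_start + 1L &&
      p$amplicon_len >= params$min_amplicon &&
      p$amplicon_len <= params$max_amplicon &&
      hairpin_score(p$fwd_seq) < params$dimer_any_limit &&
      hairpin_score(p$rev_seq) < params$dimer_any_limit &&
      interaction_score(p$fwd_seq, p$fwd_seq) < params$dimer_any_limit &&
      interaction_score(p$rev_seq, p$rev_seq) < params$dimer_any_limit &&
      interaction_score(p$fwd_seq, p$rev_seq) < params$dimer_any_limit &&
      max(interaction_score(p$fwd_seq, p$rev_seq, anchor_3p = TRUE),
          interaction_score(p$rev_seq, p$fwd_seq, anchor_3p = TRUE)) <
        params$dimer_3p_limit
    if (!ok) return(FALSE)
    if (params$mode == "span") {
      f_spans <- p$fwd_start <= j && p$fwd_end >= j + 1L
      r_spans <- p$rev_start <= j && p$rev_end >= j + 1L
      if (identical(p$spans, "forward")) {
        f_spans && !r_spans &&
          p$fwd_end - j >= params$junction_overlap_3p &&
          j - p$fwd_start + 1L >= params$junction_overlap_5p
      } else if (identical(p$spans, "reverse")) {
        r_spans && !f_spans &&
          j - p$rev_start + 1L >= params$junction_overlap_3p &&
          p$rev_end - j >= params$junction_overlap_5p
      } else FALSE
    } else {
      p$fwd_end <= j && p$rev_start >= j + 1L
    }
  }, logical(1))
}
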