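# In-silico PCR: exhaustive mismatch-bounded binding-site search, product
# prediction, classification, and the two-round cDNA -> genome screen.
#
# The binding-site engine is an exhaustive Hamming-distance search over both
# strands of every database sequence (no heuristic seeding), so every
# qualifying site is reported by construction.

.empty_sites <- function() {
  tibble(seq_id = character(), start = integer(), end = integer(),
         strand = character(), mismatches = integer(),
         mismatches_3p = integer())
}

.hamming <- function(a, b) sum(.str_chars(a) != .str_chars(b))

# database wrapper caching the DNAString conversions across many searches
.binding_db <- function(db) {
  if (inherits(db, "binding_db")) return(db)
  structure(list(chars = db,
                 dna = lapply(db, Biostrings::DNAString)),
            class = "binding_db")
}

#' Find primer binding sites in a sequence database
#'
#' Reports every window of every database sequence (both strands) within
#' `max_mismatch` Hamming mismatches of the primer over its full length.
#' `mismatches_3p` counts mismatches within the primer's `tail_3p` 3'-terminal
#' bases: for a `+` strand site that is the right end of the window, for a
#' `-` strand site the left end.
#'
#' @param primer Primer sequence 5'->3' over \{A,C,G,T\} (no `N`).
#' @param db Named character vector of uppercase sequences (e.g. from
#'   [read_genome()] or a cDNA collection).
#' @param max_mismatch Maximum total mismatches (default 3).
#' @param tail_3p Size of the 3'-terminal window for `mismatches_3p`
#'   (default 5).
#' @return Tibble: `seq_id`, `start`, `end` (1-based inclusive; `end - start
#'   + 1` equals the primer length), `strand`, `mismatches`, `mismatches_3p`.
#' @export
find_binding_sites <- function(primer, db, max_mismatch = 3L, tail_3p = 5L) {
  .assert_dna(primer, allow_n = FALSE, what = "primer")
  if (nchar(primer) == 0L) stop("primer must be non-empty", call. = FALSE)
  m <- nchar(primer)
  primer_rc <- revcomp(primer)
  win3 <- min(tail_3p, m)
  bdb <- .binding_db(db)
  out <- list()
  for (sid in names(bdb$chars)) {
    subject <- bdb$dna[[sid]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") primer else primer_rc
      hits <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mismatch)
      if (length(hits) == 0L) next
      starts <- Biostrings::start(hits); ends <- Biostrings::end(hits)
      ok <- starts >= 1L & ends <= nchar(bdb$chars[[sid]])
      starts <- starts[ok]; ends <- ends[ok]
      if (length(starts) == 0L) next
      site_seqs <- substring(bdb$chars[[sid]], starts, ends)
      cmp <- if (strand == "+") primer else primer_rc
      mm <- vapply(site_seqs, .hamming, integer(1), a = cmp, USE.NAMES = FALSE)
      mm3 <- vapply(site_seqs, function(s) {
        if (strand == "+") {
          .hamming(substr(cmp, m - win3 + 1L, m), substr(s, m - win3 + 1L, m))
        } else {
          # primer 3' terminus sits at the left (reference) end of the window
          .hamming(substr(cmp, 1L, win3), substr(s, 1L, win3))
        }
      }, integer(1), USE.NAMES = FALSE)
      out[[length(out) + 1L]] <-
        tibble(seq_id = sid, start = as.integer(starts), end = as.integer(ends),
               strand = strand, mismatches = mm, mismatches_3p = mm3)
    }
  }
  res <- if (length(out) > 0L) dplyr::bind_rows(out) else .empty_sites()
  dplyr::arrange(res, .data$seq_id, .data$start, .data$strand)
}

#' Predict amplification products from binding sites
#'
#' Emits a product for every convergent site pair on the same sequence: a
#' forward-role site on `+` with a reverse-role site on `-` ending downstream
#' (and the role-swapped orientation), with positive product length at most
#' `max_len` and zero 3'-terminal mismatches on both sites — the
#' "productive" configuration; anything else is an unproductive single-primer
#' alignment.
#'
#' @param fwd_sites,rev_sites Site tibbles from [find_binding_sites()] for
#'   the forward and reverse primer.
#' @param max_len Maximum product length in nt.
#' @return Tibble: `seq_id`, `start`, `end` (1-based inclusive product span),
#'   `length`, `orientation` (`"fr"` or `"rf"`), plus the coordinates and
#'   mismatch counts of both sites.
#' @export
predict_products <- function(fwd_sites, rev_sites, max_len = 5000L) {
  .empty_products <- function() {
    tibble(seq_id = character(), start = integer(), end = integer(),
           length = integer(), orientation = character(),
           fwd_start = integer(), fwd_end = integer(),
           rev_start = integer(), rev_end = integer(),
           fwd_mismatches = integer(), rev_mismatches = integer())
  }
  combine <- function(plus, minus, orientation) {
    if (nrow(plus) == 0L || nrow(minus) == 0L) return(NULL)
    g <- dplyr::inner_join(
      dplyr::rename(plus, p_start = "start", p_end = "end",
                    p_mm = "mismatches"),
      dplyr::rename(minus, m_start = "start", m_end = "end",
                    m_mm = "mismatches"),
      by = "seq_id", relationship = "many-to-many"
    )
    if (nrow(g) == 0L) return(NULL)
    g <- dplyr::mutate(g, length = .data$m_end - .data$p_start + 1L)
    g <- dplyr::filter(g, .data$length > 0L, .data$length <= max_len)
    if (nrow(g) == 0L) return(NULL)
    if (orientation == "fr") {
      tibble(seq_id = g$seq_id, start = g$p_start, end = g$m_end,
             length = g$length, orientation = orientation,
             fwd_start = g$p_start, fwd_end = g$p_end,
             rev_start = g$m_start, rev_end = g$m_end,
             fwd_mismatches = g$p_mm, rev_mismatches = g$m_mm)
    } else {
      tibble(seq_id = g$seq_id, start = g$p_start, end = g$m_end,
             length = g$length, orientation = orientation,
             fwd_start = g$m_start, fwd_end = g$m_end,
             rev_start = g$p_start, rev_end = g$p_end,
             fwd_mismatches = g$m_mm, rev_mismatches = g$p_mm)
    }
  }
  f0 <- dplyr::filter(fwd_sites, .data$mismatches_3p == 0L)
  r0 <- dplyr::filter(rev_sites, .data$mismatches_3p == 0L)
  res <- dplyr::bind_rows(
    combine(dplyr::filter(f0, .data$strand == "+"),
            dplyr::filter(r0, .data$strand == "-"), "fr"),
    combine(dplyr::filter(r0, .data$strand == "+"),
            dplyr::filter(f0, .data$strand == "-"), "rf")
  )
  if (nrow(res) == 0L) return(.empty_products())
  dplyr::arrange(res, .data$seq_id, .data$start, .data$end, .data$orientation)
}

#' Classify predicted products against the target gene and transcript set
#'
#' cDNA-database products on a selected transcript are `on_target`; on an
#' unselected isoform of the same gene `non_target_isoform`; on any other
#' known transcript `off_target_gene`. Genome-database products are
#' `genomic`: a junction-spanning assay should produce none, and any product
#' found on genomic sequence is potential gDNA contamination signal
#' regardless of locus.
#'
#' @param products Tibble from [predict_products()].
#' @param gene The target `gene_model`.
#' @param targets Character vector of selected transcript ids.
#' @param db `"cdna"` or `"genome"`.
#' @param tx2gene Optional named character vector mapping additional (decoy /
#'   other-gene) transcript ids to their gene ids; a cDNA product on a
#'   sequence id absent from both the gene and this map is a database /
#'   annotation mismatch and is fatal.
#' @return `products` with a `category` column.
#' @export
classify_products <- function(products, gene, targets, db = c("cdna", "genome"),
                              tx2gene = NULL) {
  db <- match.arg(db)
  stopifnot(inherits(gene, "gene_model"))
  if (db == "genome") {
    return(dplyr::mutate(products, category = rep("genomic", nrow(products))))
  }
  own <- names(gene$transcripts)
  cat <- character(nrow(products))
  for (i in seq_len(nrow(products))) {
    sid <- products$seq_id[i]
    if (sid %in% targets) {
      cat[i] <- "on_target"
    } else if (sid %in% own) {
      cat[i] <- "non_target_isoform"
    } else if (!is.null(tx2gene) && sid %in% names(tx2gene)) {
      cat[i] <- "off_target_gene"
    } else {
      stop("cDNA product on unknown sequence id '", sid,
           "': database/annotation mismatch", call. = FALSE)
    }
  }
  dplyr::mutate(products, category = cat)
}

# sites not participating in any predicted product of the same database
.unproductive <- function(sites, products, role) {
  if (nrow(sites) == 0L) return(sites)
  if (nrow(products) == 0L) return(sites)
  used <- if (role == "forward") {
    products[, c("seq_id", "fwd_start", "fwd_end")] |>
      dplyr::rename(start = "fwd_start", end = "fwd_end")
  } else {
    products[, c("seq_id", "rev_start", "rev_end")] |>
      dplyr::rename(start = "rev_start", end = "rev_end")
  }
  dplyr::anti_join(sites, dplyr::distinct(used),
                   by = c("seq_id", "start", "end"))
}

# full screen of one pair against one database; `cache` (an environment)
# de-duplicates site searches across pairs sharing a primer
.screen_pair <- function(fwd_seq, rev_seq, db, max_mismatch, max_len,
                         cache = NULL, cache_tag = "") {
  get_sites <- function(primer) {
    if (is.null(cache)) {
      return(find_binding_sites(primer, db, max_mismatch = max_mismatch))
    }
    key <- paste0(cache_tag, primer)
    hit <- cache[[key]]
    if (is.null(hit)) {
      hit <- find_binding_sites(primer, db, max_mismatch = max_mismatch)
      assign(key, hit, envir = cache)
    }
    hit
  }
  fs <- get_sites(fwd_seq)
  rs <- get_sites(rev_seq)
  prods <- predict_products(fs, rs, max_len = max_len)
  unprod <- dplyr::bind_rows(
    dplyr::mutate(.unproductive(fs, prods, "forward"), primer_role = "forward"),
    dplyr::mutate(.unproductive(rs, prods, "reverse"), primer_role = "reverse")
  )
  list(products = prods, unproductive = unprod)
}

#' Two-round in-silico PCR specificity screen
#'
#' Round 1 screens every pair against the spliced-transcript (cDNA) database
#' — the nucleic-acid species actually present in an RT-qPCR reaction — and
#' classifies each product. Pairs with any `off_target_gene` product fail
#' round 1, unless every pair has one, in which case all are retained and
#' flagged so the user can make an informed decision. The best `top_n`
#' round-1 survivors (lowest penalty, then fewest products) advance to round
#' 2, a genomic screen: genomic products down-rank a pair (they never
#' silently remove it). Unproductive single-primer alignments from both
#' rounds are retained on every report.
#'
#' @param pairs Tibble from [generate_pairs()] (any subset of its rows).
#' @param cdna_db Named character vector of spliced transcript sequences
#'   (target gene isoforms plus any decoy transcripts).
#' @param genome_db Named character vector of genomic sequences.
#' @param gene Target `gene_model`.
#' @param targets Selected transcript ids.
#' @param tx2gene Named map for non-target cDNA sequence ids (see
#'   [classify_products()]).
#' @param max_mismatch Mismatch tolerance of the site search (default 3).
#' @param max_offtarget_cdna,max_offtarget_genome Product length caps per
#'   database (defaults 2000 / 5000 nt).
#' @param top_n Number of round-1 survivors screened genomically (default 10).
#' @return Tibble: the input pair columns plus `pair_id`, product-category
#'   counts, `n_unproductive`, `pass_round1`, `all_pairs_flagged`,
#'   `screened_round2`, `pass_round2`, and list-columns `products` and
#'   `unproductive_hits`.
#' @export
two_round_filter <- function(pairs, cdna_db, genome_db, gene, targets,
                             tx2gene = NULL, max_mismatch = 3L,
                             max_offtarget_cdna = 2000L,
                             max_offtarget_genome = 5000L, top_n = 10L) {
  if (nrow(pairs) == 0L) stop("no primer pairs to screen", call. = FALSE)
  if (length(if (inherits(cdna_db, "binding_db")) cdna_db$chars else cdna_db) == 0L ||
      length(if (inherits(genome_db, "binding_db")) genome_db$chars else genome_db) == 0L) {
    stop("specificity databases must be non-empty", call. = FALSE)
  }
  pairs <- dplyr::mutate(pairs,
                         pair_id = sprintf("pair_%03d", seq_len(nrow(pairs))))
  cdna_db <- .binding_db(cdna_db)
  genome_db <- .binding_db(genome_db)
  cache <- new.env(parent = emptyenv())
  r1 <- purrr::map(seq_len(nrow(pairs)), function(i) {
    sc <- .screen_pair(pairs$fwd_seq[i], pairs$rev_seq[i], cdna_db,
                       max_mismatch, max_offtarget_cdna,
                       cache = cache, cache_tag = "cdna|")
    sc$products <- classify_products(sc$products, gene, targets,
                                     db = "cdna", tx2gene = tx2gene)
    sc
  })
  n_off_gene <- vapply(r1, function(x) sum(x$products$category == "off_target_gene"),
                       integer(1))
  all_flagged <- all(n_off_gene > 0L)
  pass1 <- n_off_gene == 0L | all_flagged
  n_products_r1 <- vapply(r1, function(x) nrow(x$products), integer(1))
  # best round-1 survivors advance to the genomic round
  surv <- which(pass1)
  surv <- surv[order(pairs$pair_penalty[surv], n_products_r1[surv],
                     pairs$pair_id[surv])]
  advance <- utils::head(surv, top_n)
  r2 <- vector("list", nrow(pairs))
  for (i in advance) {
    sc <- .screen_pair(pairs$fwd_seq[i], pairs$rev_seq[i], genome_db,
                       max_mismatch, max_offtarget_genome,
                       cache = cache, cache_tag = "genome|")
    sc$products <- classify_products(sc$products, gene, targets, db = "genome")
    r2[[i]] <- sc
  }
  combine_reports <- function(i) {
    prods <- dplyr::bind_rows(
      dplyr::mutate(r1[[i]]$products, db = "cdna"),
      if (!is.null(r2[[i]])) dplyr::mutate(r2[[i]]$products, db = "genome")
    )
    unprod <- dplyr::bind_rows(
      dplyr::mutate(r1[[i]]$unproductive, db = "cdna"),
      if (!is.null(r2[[i]])) dplyr::mutate(r2[[i]]$unproductive, db = "genome")
    )
    list(products = prods, unproductive = unprod)
  }
  reports <- purrr::map(seq_len(nrow(pairs)), combine_reports)
  count_cat <- function(rep, what) sum(rep$products$category == what)
  out <- dplyr::mutate(
    pairs,
    n_on_target = vapply(reports, count_cat, integer(1), what = "on_target"),
    n_non_target_isoform = vapply(reports, count_cat, integer(1),
                                  what = "non_target_isoform"),
    n_off_target_gene = vapply(reports, count_cat, integer(1),
                               what = "off_target_gene"),
    n_genomic = vapply(reports, count_cat, integer(1), what = "genomic"),
    n_unproductive = vapply(reports, function(r) nrow(r$unproductive), integer(1)),
    pass_round1 = pass1,
    all_pairs_flagged = all_flagged,
    screened_round2 = seq_len(nrow(pairs)) %in% advance,
    pass_round2 = dplyr::if_else(.data$screened_round2,
                                 .data$n_genomic == 0L, NA),
    products = purrr::map(reports, "products"),
    unproductive_hits = purrr::map(reports, "unproductive")
  )
  out
}
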