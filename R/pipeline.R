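# End-to-end design: annotation -> junction selection -> masking -> primer
# enumeration -> two-round specificity screen -> ranked report.

# junctions actually passed to primer design: the perfect set, or all
# junctions tying with the top-ranked fallback junction
.design_junctions <- function(selection) {
  jx <- selection$junctions
  if (selection$perfect || nrow(jx) <= 1L) return(jx)
  top <- jx[1L, ]
  dplyr::filter(jx, .data$coverage == top$coverage,
                .data$leakage == top$leakage,
                .data$on_canonical == top$on_canonical)
}

# transcript whose cDNA serves as design template for a junction: canonical
# if it contains the junction, else the alphabetically first target that does
.template_transcript <- function(gene, targets, donor, acceptor) {
  cands <- c(gene$canonical_id, sort(targets), sort(names(gene$transcripts)))
  for (id in unique(cands)) {
    tr <- gene$transcripts[[id]]
    if (!is.na(.junction_cdna_pos(tr, donor, acceptor))) return(id)
  }
  NA_character_
}

#' Design transcript-specific junction primers end to end
#'
#' Runs the full pipeline for one gene: junction selection for the chosen
#' transcripts, common-variant masking of the design template, exhaustive
#' junction-anchored pair enumeration, and the two-round in-silico PCR
#' specificity screen (spliced transcripts first, then genomic sequence).
#'
#' @param genome Genome FASTA path or named vector from [read_genome()].
#' @param annotation GTF/GFF path, or a pre-built list of `gene_model`s from
#'   [read_gene_models()].
#' @param gene Gene id (or gene name) to design for.
#' @param targets Transcript ids to detect, or `"ALL"` (default).
#' @param vcf Optional VCF of common variants; when supplied, primers may not
#'   overlap any position at/above `maf`.
#' @param maf Allele-frequency threshold for masking (default 0.01).
#' @param af_key INFO key holding allele frequencies (default `"AF"`).
#' @param params [design_params()].
#' @param decoys Optional named vector of additional (other-gene) transcript
#'   sequences added to the cDNA screening database.
#' @param tx2gene Named map from decoy sequence id to gene id (defaults to
#'   each decoy mapping to itself).
#' @param weights [score_weights()].
#' @param max_mismatch,top_n,max_offtarget_cdna,max_offtarget_genome Passed
#'   to [two_round_filter()].
#' @return A `primer_design` object: `rows` (ranked report tibble),
#'   `screened` (full per-pair screen), `selection`, `rejections`, plus the
#'   inputs needed to reproduce the run. `tidy()` returns the report rows,
#'   `glance()` a one-row run summary, `autoplot()` an amplicon/score plot.
#' @export
design_primers <- function(genome, annotation, gene, targets = "ALL",
                           vcf = NULL, maf = 0.01, af_key = "AF",
                           params = design_params(), decoys = NULL,
                           tx2gene = NULL, weights = score_weights(),
                           max_mismatch = 3L, top_n = 10L,
                           max_offtarget_cdna = 2000L,
                           max_offtarget_genome = 5000L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_genome(genome)
  }
  models <- if (is.character(annotation)) read_gene_models(annotation, genome)
            else annotation
  gm <- models[[gene]]
  if (is.null(gm)) {
    by_name <- purrr::keep(models, ~ identical(.x$gene_name, gene))
    if (length(by_name) == 1L) gm <- by_name[[1L]]
  }
  if (is.null(gm)) stop("gene '", gene, "' not found in annotation", call. = FALSE)
  selection <- select_junctions(gm, targets)
  targets <- selection$targets
  mask <- if (is.null(vcf)) empty_variant_mask(maf) else
    load_common_variants(vcf, threshold = maf, af_key = af_key)

  jx <- .design_junctions(selection)
  all_pairs <- list()
  rejections <- .new_rejections()
  for (i in seq_len(nrow(jx))) {
    tmpl_id <- .template_transcript(gm, targets, jx$donor[i], jx$acceptor[i])
    if (is.na(tmpl_id)) next
    tr <- gm$transcripts[[tmpl_id]]
    template <- apply_mask(tr, mask)
    jpos <- .junction_cdna_pos(tr, jx$donor[i], jx$acceptor[i])
    pairs <- generate_pairs(template, jpos, params)
    rejections <- rejections + attr(pairs, "rejections")
    if (nrow(pairs) > 0L) {
      all_pairs[[length(all_pairs) + 1L]] <-
        dplyr::mutate(pairs, junction_id = jx$junction_id[i],
                      template_transcript = tmpl_id)
    }
  }
  pairs <- if (length(all_pairs) > 0L) dplyr::bind_rows(all_pairs) else NULL

  if (is.null(pairs) || nrow(pairs) == 0L) {
    out <- structure(
      list(gene = gm, targets = targets, selection = selection,
           params = params, mask = mask, weights = weights,
           screened = NULL, rows = build_result_rows(.empty_screened(), weights),
           rejections = rejections, status = "no_candidates"),
      class = "primer_design")
    return(out)
  }

  cdna_db <- vapply(gm$transcripts, `[[`, "", "cdna")
  if (!is.null(decoys) && length(decoys) > 0L) {
    if (is.null(tx2gene)) tx2gene <- setNames(names(decoys), names(decoys))
    cdna_db <- c(cdna_db, decoys)
  }
  screened <- two_round_filter(pairs, cdna_db, genome, gm, targets,
                               tx2gene = tx2gene, max_mismatch = max_mismatch,
                               max_offtarget_cdna = max_offtarget_cdna,
                               max_offtarget_genome = max_offtarget_genome,
                               top_n = top_n)
  rows <- build_result_rows(screened, weights)
  status <- if (all(!screened$pass_round1) ||
                (all(screened$all_pairs_flagged))) "all_flagged"
            else "ok"
  structure(
    list(gene = gm, targets = targets, selection = selection, params = params,
         mask = mask, weights = weights, screened = screened, rows = rows,
         rejections = rejections, status = status),
    class = "primer_design")
}

# an empty screened tibble so report building degrades gracefully
.empty_screened <- function() {
  tibble(pair_id = character(), junction_id = character(),
         fwd_seq = character(), rev_seq = character(),
         amplicon_len = integer(), fwd_tm = numeric(), rev_tm = numeric(),
         fwd_gc = numeric(), rev_gc = numeric(), pair_penalty = numeric(),
         n_on_target = integer(), n_non_target_isoform = integer(),
         n_off_target_gene = integer(), n_genomic = integer(),
         n_unproductive = integer(), pass_round1 = logical(),
         pass_round2 = logical(), products = list(),
         unproductive_hits = list())
}

#' @export
print.primer_design <- function(x, ...) {
  cat("<primer_design> gene ", x$gene$gene_id, ", targets: ",
      paste(x$targets, collapse = ","), "\n", sep = "")
  cat("  junction selection: ",
      if (x$selection$perfect) "perfect" else "best-effort", ", ",
      nrow(x$selection$junctions), " junction(s)\n", sep = "")
  cat("  ", nrow(x$rows), " ranked pair(s), status: ", x$status, "\n", sep = "")
  if (nrow(x$rows) > 0L) print(utils::head(x$rows, 5L))
  invisible(x)
}

#' @rdname design_primers
#' @param x A `primer_design` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.primer_design <- function(x, ...) x$rows

#' @rdname design_primers
#' @exportS3Method generics::glance
glance.primer_design <- function(x, ...) {
  tibble(gene_id = x$gene$gene_id,
         n_targets = length(x$targets),
         perfect_junctions = x$selection$perfect,
         n_pairs = nrow(x$rows),
         n_pass_round1 = if (is.null(x$screened)) 0L else
           sum(x$screened$pass_round1),
         n_clean_genomic = if (is.null(x$screened)) 0L else
           sum(x$screened$pass_round2 %in% TRUE),
         best_score = if (nrow(x$rows) > 0L) min(x$rows$final_score) else NA_real_,
         status = x$status)
}

#' Plot ranked primer pairs of a design
#'
#' Amplicon spans along the design template, best-ranked pair at the top,
#' coloured by final score, with junction-spanning primer footprints marked.
#'
#' @param object A `primer_design` object.
#' @param top Number of top-ranked pairs to draw (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.primer_design <- function(object, top = 10L, ...) {
  stopifnot(nrow(object$rows) > 0L)
  sc <- object$screened
  sc$final_score <- final_score(sc, object$weights)
  sc <- dplyr::arrange(sc, .data$final_score, .data$amplicon_len, .data$pair_id)
  sc <- utils::head(sc, top)
  sc$rank <- factor(rev(seq_len(nrow(sc))), levels = seq_len(nrow(sc)),
                    labels = rev(sc$pair_id))
  ggplot2::ggplot(sc) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$amplicon_start,
                                       xend = .data$amplicon_end,
                                       y = .data$rank, yend = .data$rank,
                                       colour = .data$final_score),
                          linewidth = 3, lineend = "butt") +
    ggplot2::geom_vline(xintercept = sc$junction_pos[1L], linetype = "dashed") +
    ggplot2::scale_colour_viridis_c(name = "final score", direction = -1) +
    ggplot2::labs(x = "template position (nt)", y = NULL,
                  title = paste("Ranked primer pairs,", object$gene$gene_id),
                  subtitle = "dashed line: targeted exon-exon junction") +
    ggplot2::theme_minimal()
}

#' Heatmap of the junction-by-transcript incidence matrix
#'
#' @param gene A `gene_model`.
#' @return A ggplot tile plot: which transcripts contain which junction.
#' @export
plot_junction_matrix <- function(gene) {
  m <- junction_matrix(gene)
  df <- as_tibble(as.data.frame.table(m, responseName = "present"))
  names(df)[1:2] <- c("junction", "transcript")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$transcript, y = .data$junction,
                                   fill = factor(.data$present))) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(`0` = "grey90", `1` = "#2c7fb8"),
                               name = "contains") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste("Junction incidence,", gene$gene_id)) +
    ggplot2::theme_minimal()
}
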