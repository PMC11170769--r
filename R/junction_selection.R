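# Junction selection: find junctions present in every selected transcript and
# absent from every unselected one, with a ranked fallback when none exist.

#' Junction-by-transcript incidence matrix
#'
#' @param gene A `gene_model`.
#' @return Binary integer matrix, one row per junction (named by junction id,
#'   ordered by genomic coordinate) and one column per transcript (ordered by
#'   transcript id); entry 1 iff the transcript contains the junction.
#' @export
junction_matrix <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  jx <- enumerate_junctions(gene)
  tr_ids <- sort(names(gene$transcripts))
  m <- matrix(0L, nrow = nrow(jx), ncol = length(tr_ids),
              dimnames = list(jx$junction_id, tr_ids))
  for (k in seq_len(nrow(jx))) m[k, jx$transcript_ids[[k]]] <- 1L
  m
}

#' Select discriminating exon-exon junctions
#'
#' Finds junctions contained in all `targets` and in no unselected transcript
#' of the gene ("perfect" junctions). When none exist, all junctions are
#' returned ranked by: higher target coverage, lower leakage into unselected
#' transcripts, presence on the canonical transcript, then smaller genomic
#' donor coordinate; warnings list the unselected transcripts detected by the
#' top-ranked junction and the targets it misses.
#'
#' @param gene A `gene_model`.
#' @param targets Character vector of transcript ids to detect, or `"ALL"`.
#' @return A `junction_selection`: list with `junctions` (tibble with
#'   `junction_id`, `coverage`, `leakage`, `on_canonical` and coordinates),
#'   `perfect` flag, `warnings` tibble (`transcript_id`,
#'   `kind` in `non_targeted_detected` / `target_not_detected`), `targets`,
#'   and `gene_id`.
#' @export
select_junctions <- function(gene, targets) {
  stopifnot(inherits(gene, "gene_model"))
  all_ids <- names(gene$transcripts)
  if (length(targets) == 1L && identical(toupper(targets), "ALL")) targets <- all_ids
  targets <- unique(targets)
  if (length(targets) == 0L) stop("targets must be non-empty", call. = FALSE)
  unknown <- setdiff(targets, all_ids)
  if (length(unknown) > 0L) {
    stop("target transcript(s) not in gene ", gene$gene_id, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  jx <- enumerate_junctions(gene)
  if (nrow(jx) == 0L) {
    stop("gene ", gene$gene_id, " has no exon-exon junction (single-exon ",
         "transcripts only); junction-anchored design is impossible",
         call. = FALSE)
  }
  unselected <- setdiff(all_ids, targets)
  canonical <- gene$canonical_id
  scored <- jx |>
    dplyr::mutate(
      coverage = purrr::map_int(.data$transcript_ids,
                                ~ length(intersect(.x, targets))),
      leakage = purrr::map_int(.data$transcript_ids,
                               ~ length(intersect(.x, unselected))),
      on_canonical = purrr::map_lgl(.data$transcript_ids,
                                    ~ canonical %in% .x)
    )
  perfect_rows <- scored$coverage == length(targets) & scored$leakage == 0L
  if (any(perfect_rows)) {
    chosen <- scored[perfect_rows, ]
    warnings <- tibble(transcript_id = character(), kind = character())
    perfect <- TRUE
  } else {
    chosen <- dplyr::arrange(scored, dplyr::desc(.data$coverage), .data$leakage,
                             dplyr::desc(.data$on_canonical), .data$donor,
                             .data$acceptor)
    top <- chosen$transcript_ids[[1L]]
    warnings <- dplyr::bind_rows(
      tibble(transcript_id = intersect(top, unselected),
             kind = "non_targeted_detected"),
      tibble(transcript_id = setdiff(targets, top),
             kind = "target_not_detected")
    )
    perfect <- FALSE
  }
  structure(
    list(junctions = dplyr::select(chosen, "junction_id", "chrom", "donor",
                                   "acceptor", "strand", "coverage", "leakage",
                                   "on_canonical"),
         perfect = perfect, warnings = warnings,
         targets = targets, gene_id = gene$gene_id),
    class = "junction_selection"
  )
}

#' @export
print.junction_selection <- function(x, ...) {
  cat("<junction_selection> gene ", x$gene_id, ", ",
      length(x$targets), " target(s), ",
      nrow(x$junctions), " junction(s), ",
      if (x$perfect) "perfect" else "best-effort", "\n", sep = "")
  print(x$junctions)
  if (nrow(x$warnings) > 0L) {
    cat("warnings:\n"); print(x$warnings)
  }
  invisible(x)
}

#' @rdname select_junctions
#' @param x A `junction_selection`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.junction_selection <- function(x, ...) x$junctions

#' @rdname select_junctions
#' @exportS3Method generics::glance
glance.junction_selection <- function(x, ...) {
  tibble(gene_id = x$gene_id, n_targets = length(x$targets),
         n_junctions = nrow(x$junctions), perfect = x$perfect,
         n_warnings = nrow(x$warnings))
}
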