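# Final scoring, ranked result rows, and lossless tabular output.

#' Scoring weights for specificity findings
#'
#' @param w_iso Penalty per product on a non-targeted isoform of the gene.
#' @param w_gene Penalty per product on another gene's transcript.
#' @param w_gen Penalty per genomic product.
#' @param w_unprod Penalty per unproductive single-primer alignment.
#' @return Named numeric vector of weights.
#' @export
score_weights <- function(w_iso = 2, w_gene = 5, w_gen = 3, w_unprod = 0.1) {
  c(w_iso = w_iso, w_gene = w_gene, w_gen = w_gen, w_unprod = w_unprod)
}

#' Final score of screened primer pairs
#'
#' `final_score = pair_penalty + w_iso * #non_target_isoform +
#' w_gene * #off_target_gene + w_gen * #genomic + w_unprod * #unproductive`.
#' Lower is better; a clean pair at the thermodynamic optimum scores 0.
#'
#' @param screened Tibble from [two_round_filter()] (needs `pair_penalty` and
#'   the product-category counts).
#' @param weights From [score_weights()].
#' @return Numeric vector of final scores, one per row.
#' @export
final_score <- function(screened, weights = score_weights()) {
  screened$pair_penalty +
    weights[["w_iso"]] * screened$n_non_target_isoform +
    weights[["w_gene"]] * screened$n_off_target_gene +
    weights[["w_gen"]] * screened$n_genomic +
    weights[["w_unprod"]] * screened$n_unproductive
}

.collapse_ids <- function(x) paste(sort(unique(x)), collapse = ";")

#' Build the ranked result table
#'
#' One row per screened pair, sorted by `final_score` ascending with
#' deterministic tie-breaks (amplicon length, then pair id). Temperatures and
#' scores are fixed at two decimals so the written report round-trips
#' exactly.
#'
#' @param screened Tibble from [two_round_filter()] (optionally carrying a
#'   `junction_id` column from the design stage).
#' @param weights From [score_weights()].
#' @return Tibble of result rows.
#' @export
build_result_rows <- function(screened, weights = score_weights()) {
  det <- function(rep, what) {
    .collapse_ids(rep$seq_id[rep$category == what])
  }
  rows <- tibble(
    pair_id = screened$pair_id,
    junction = if ("junction_id" %in% names(screened)) screened$junction_id
               else "",
    fwd_seq = screened$fwd_seq,
    rev_seq = screened$rev_seq,
    amplicon_len = as.integer(screened$amplicon_len),
    fwd_tm = round(screened$fwd_tm, 2),
    rev_tm = round(screened$rev_tm, 2),
    fwd_gc = round(screened$fwd_gc, 2),
    rev_gc = round(screened$rev_gc, 2),
    pair_penalty = round(screened$pair_penalty, 2),
    final_score = round(final_score(screened, weights), 2),
    detected = vapply(screened$products, det, "", what = "on_target"),
    non_target_isoforms = vapply(screened$products, det, "",
                                 what = "non_target_isoform"),
    off_target_genes = vapply(screened$products, det, "",
                              what = "off_target_gene"),
    n_genomic = as.integer(screened$n_genomic),
    n_unproductive = as.integer(screened$n_unproductive),
    pass_round1 = screened$pass_round1,
    pass_round2 = screened$pass_round2
  )
  dplyr::arrange(rows, .data$final_score, .data$amplicon_len, .data$pair_id)
}

#' Write a result table to CSV, TSV or JSON
#'
#' The written file re-parses to a table equal to the input (fields are
#' already fixed-precision, so the decimal text representation is exact).
#' An empty table writes a header-only file (or `[]` for JSON).
#'
#' @param rows Tibble from [build_result_rows()].
#' @param path Output path.
#' @param format `"csv"`, `"tsv"` or `"json"` (default from the file
#'   extension, falling back to csv).
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path, format = c("auto", "csv", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "tsv", "json")) ext else "csv"
  }
  switch(format,
    csv = readr::write_csv(rows, path, progress = FALSE),
    tsv = readr::write_tsv(rows, path, progress = FALSE),
    json = jsonlite::write_json(rows, path, dataframe = "rows",
                                auto_unbox = FALSE, digits = NA, na = "null")
  )
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path File path.
#' @param format As in [write_report()].
#' @return Tibble with the same columns and values as the written table.
#' @export
read_report <- function(path, format = c("auto", "csv", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "tsv", "json")) ext else "csv"
  }
  spec <- readr::cols(
    pair_id = readr::col_character(),
    junction = readr::col_character(),
    fwd_seq = readr::col_character(),
    rev_seq = readr::col_character(),
    amplicon_len = readr::col_integer(),
    fwd_tm = readr::col_double(),
    rev_tm = readr::col_double(),
    fwd_gc = readr::col_double(),
    rev_gc = readr::col_double(),
    pair_penalty = readr::col_double(),
    final_score = readr::col_double(),
    detected = readr::col_character(),
    non_target_isoforms = readr::col_character(),
    off_target_genes = readr::col_character(),
    n_genomic = readr::col_integer(),
    n_unproductive = readr::col_integer(),
    pass_round1 = readr::col_logical(),
    pass_round2 = readr::col_logical()
  )
  out <- switch(format,
    csv = readr::read_csv(path, col_types = spec, progress = FALSE),
    tsv = readr::read_tsv(path, col_types = spec, progress = FALSE),
    json = {
      x <- jsonlite::fromJSON(path)
      if (length(x) == 0L) {
        tibble()
      } else {
        for (cc in c("amplicon_len", "n_genomic", "n_unproductive")) {
          x[[cc]] <- as.integer(x[[cc]])
        }
        for (cc in c("fwd_tm", "rev_tm", "fwd_gc", "rev_gc", "pair_penalty",
                     "final_score")) {
          x[[cc]] <- as.numeric(x[[cc]])
        }
        as_tibble(x)
      }
    }
  )
  # readr reads empty strings as NA; the table uses "" for "none"
  chr <- c("detected", "non_target_isoforms", "off_target_genes", "junction")
  for (cc in intersect(chr, names(out))) {
    out[[cc]][is.na(out[[cc]])] <- ""
  }
  out
}
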