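# Peptide-to-kinase map construction.
#
# Candidate upstream kinases for each phosphorylatable peptide come from a
# homology-based prediction table (score, per-peptide rank) plus
# in-vitro-confirmed kinase-substrate pairs, which carry rank 0. The
# homology search that produces the candidate table queries a proprietary
# external database and is treated as an input, not re-implemented.

#' Build the retained peptide-to-kinase map
#'
#' A candidate row is retained iff its peptide passes QC AND it is either
#' in-vitro confirmed (rank 0) or has prediction `score > score_min` with
#' `1 <= rank <= max_rank`. Both score and rank comparisons follow the
#' strict reading of "greater than 300 and rank ordered in the top 12":
#' a score of exactly 300 or a rank of 13 is excluded; in-vitro rows bypass
#' the score filter entirely. The rank is interpreted per peptide (each
#' peptide's candidate kinases are rank-ordered) and taken as given.
#'
#' Each row's retention decision depends only on that row, so the map is
#' invariant to input order; duplicated (kinase, peptide) pairs are
#' collapsed. Candidates referencing peptides absent from the value table
#' are skipped with a warning.
#'
#' @param candidates Tibble with columns `kinase_id`, `peptide_id`, `score`,
#'   `rank`, `in_vitro`.
#' @param values Output of [qc_filter()] (used both as the peptide universe
#'   and for QC flags), or a character vector of QC-passing peptide ids.
#' @param score_min Exclusive score threshold (default 300).
#' @param max_rank Maximum retained rank (default 12).
#' @return A tibble `kinase_id`, `peptide_id`, `score`, `rank`, `in_vitro`,
#'   sorted by kinase then peptide; kinases with no retained peptide are
#'   absent.
#' @export
#' @examples
#' cand <- tibble::tibble(
#'   kinase_id = "JAK1", peptide_id = c("P001", "P002", "P003"),
#'   score = c(301, 300, 0), rank = c(5L, 1L, 0L),
#'   in_vitro = c(FALSE, FALSE, TRUE)
#' )
#' build_kinase_map(cand, c("P001", "P002", "P003"))
build_kinase_map <- function(candidates, values, score_min = 300,
                             max_rank = 12) {
  check_columns(candidates, c("kinase_id", "peptide_id", "score", "rank",
                              "in_vitro"), "`candidates`")
  if (any(candidates$rank < 0)) abort("`rank` must be >= 0")
  if (any(candidates$in_vitro != (candidates$rank == 0))) {
    abort("`in_vitro` must be TRUE exactly when `rank` is 0")
  }
  score_min <- check_number(score_min, "score_min")
  max_rank <- check_number(max_rank, "max_rank", min = 1)

  if (is.character(values)) {
    universe <- values
    qc_set <- values
  } else {
    check_columns(values, c("peptide_id", "qc_pass"), "`values`")
    universe <- unique(values$peptide_id)
    qc_set <- qc_passing(values)
  }

  unknown <- !(candidates$peptide_id %in% universe)
  if (any(unknown)) {
    warn(sprintf("skipping %d candidate row(s) referencing unknown peptides",
                 sum(unknown)))
    candidates <- candidates[!unknown, ]
  }

  retained <- candidates %>%
    filter(.data$peptide_id %in% qc_set) %>%
    filter(retention_rule(., score_min = score_min, max_rank = max_rank)) %>%
    distinct(.data$kinase_id, .data$peptide_id, .keep_all = TRUE) %>%
    arrange(.data$kinase_id, .data$peptide_id)

  if (nrow(retained) == 0L) {
    abort(paste(
      "no candidate passed the retention filter;",
      "review `score_min`/`max_rank` and the QC thresholds"
    ))
  }
  retained
}
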