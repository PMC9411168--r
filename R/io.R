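# Plain-text interchange formats: TSV tables, SIF edge lists, GMT gene
# sets, JSON ground truth / run reports.

#' Read and write the long-format signal table
#'
#' Columns: `sample_id`, `group`, `peptide_id`, `exposure_ms`, `signal`.
#' @param path File path.
#' @param signals Tibble to write.
#' @return `read_signals()` returns a tibble; the writers return `path`
#'   invisibly.
#' @export
read_signals <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = "c", group = "c", peptide_id = "c",
                    exposure_ms = "d", signal = "d"
                  ))
}

#' @rdname read_signals
#' @export
write_signals <- function(signals, path) {
  check_columns(signals, c("sample_id", "group", "peptide_id",
                           "exposure_ms", "signal"), "`signals`")
  readr::write_tsv(signals, path)
  invisible(path)
}

#' Read and write kinase candidate tables
#'
#' Columns: `kinase_id`, `peptide_id`, `score`, `rank`, `in_vitro`.
#' @inheritParams read_signals
#' @param candidates Tibble to write.
#' @export
read_candidates <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    kinase_id = "c", peptide_id = "c", score = "d",
                    rank = "i", in_vitro = "l"
                  ))
}

#' @rdname read_candidates
#' @export
write_candidates <- function(candidates, path) {
  check_columns(candidates, c("kinase_id", "peptide_id", "score", "rank",
                              "in_vitro"), "`candidates`")
  readr::write_tsv(candidates, path)
  invisible(path)
}

#' Write the peptide value matrix as a wide TSV
#'
#' Rows are peptides, columns samples, entries the reduced log2 values; a
#' companion QC column records the per-peptide pass flag.
#' @param values Output of [qc_filter()].
#' @param path File path.
#' @export
write_values_wide <- function(values, path) {
  check_columns(values, c("sample_id", "peptide_id", "value", "qc_pass"),
                "`values`")
  wide <- values %>%
    select("peptide_id", "qc_pass", "sample_id", "value") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value") %>%
    arrange(.data$peptide_id)
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read and write SIF-style edge lists
#'
#' Simple interaction format: whitespace/tab-separated
#' `node_a interaction node_b`; a two-column file is read with the
#' interaction type `"unspecified"`.
#' @inheritParams read_signals
#' @param edges Tibble with `node_a`, `node_b` and optionally
#'   `interaction`.
#' @export
read_sif <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- lengths(parts) < 2L
  if (any(bad)) abort(sprintf("malformed SIF line: '%s'", lines[bad][1]))
  tibble(
    node_a = vapply(parts, `[`, character(1), 1L),
    interaction = vapply(parts, function(p) {
      if (length(p) >= 3L) p[2L] else "unspecified"
    }, character(1)),
    node_b = vapply(parts, function(p) p[length(p)], character(1))
  )
}

#' @rdname read_sif
#' @export
write_sif <- function(edges, path) {
  check_columns(edges, c("node_a", "node_b"), "`edges`")
  interaction <- if ("interaction" %in% names(edges)) {
    edges$interaction
  } else {
    rep("unspecified", nrow(edges))
  }
  readr::write_lines(paste(edges$node_a, interaction, edges$node_b,
                           sep = "\t"), path)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' Each line is `set_name <TAB> description <TAB> member...`. Reading
#' returns a long tibble (`pathway_id`, `kinase_id`) suitable for
#' [rank_pathways()].
#' @inheritParams read_signals
#' @param sets Long tibble `pathway_id`, `kinase_id`.
#' @param descriptions Optional named character vector of per-set
#'   descriptions.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) abort(sprintf("malformed GMT line: '%s'", lines[bad][1]))
  bind_rows(purrr::map(parts, function(p) {
    tibble(pathway_id = p[1L], kinase_id = p[-(1:2)])
  }))
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  check_columns(sets, c("pathway_id", "kinase_id"), "`sets`")
  split_sets <- split(sets$kinase_id, sets$pathway_id)
  lines <- vapply(names(split_sets), function(nm) {
    desc <- descriptions[nm] %||% "na"
    paste(c(nm, unname(desc), sort(unique(split_sets[[nm]]))),
          collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read and write phosphosite intensity tables
#'
#' Columns: `site_id`, `sample_id`, `group`, `log_intensity`.
#' @inheritParams read_signals
#' @param intensities Tibble to write.
#' @export
read_phosphosites <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    site_id = "c", sample_id = "c", group = "c",
                    log_intensity = "d"
                  ))
}

#' @rdname read_phosphosites
#' @export
write_phosphosites <- function(intensities, path) {
  check_columns(intensities, c("site_id", "sample_id", "group",
                               "log_intensity"), "`intensities`")
  readr::write_tsv(intensities, path)
  invisible(path)
}

#' Write ground truth or a run report as JSON
#'
#' @param x A list (e.g. `simulate_array_experiment()$truth` or a pipeline
#'   run report).
#' @param path File path.
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
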