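#' Compare context statistics between two species
#'
#' Joins two context-statistics tables (which must cover the same context
#' universe) and reports per-context differences of mutation bias and
#' minimal contrast, `A - B` as labelled. Contexts undefined in either
#' table are flagged; `compare_stats(a, b)` and `compare_stats(b, a)` are
#' sign-flips of each other.
#'
#' @param a,b Tibbles with columns `context`, `mutation_bias`,
#'   `minimal_contrast` (e.g. from [context_statistics()] or a reference
#'   table of published values).
#' @param labels Length-2 character vector naming the two sets.
#' @return A tibble: `context`, `bias_a`, `bias_b`, `mc_a`, `mc_b`,
#'   `bias_diff`, `mc_diff`, `defined` (TRUE when all four inputs are
#'   defined), sorted by decreasing `|bias_diff|`.
#' @export
compare_stats <- function(a, b, labels = c("A", "B")) {
  only_a <- setdiff(a$context, b$context)
  only_b <- setdiff(b$context, a$context)
  if (length(only_a) || length(only_b)) {
    abort_ctx(
      "context universes differ (only in %s: %d, e.g. %s; only in %s: %d, e.g. %s)",
      labels[1], length(only_a), paste(utils::head(only_a, 3), collapse = " "),
      labels[2], length(only_b), paste(utils::head(only_b, 3), collapse = " ")
    )
  }
  out <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(a), "context",
      bias_a = "mutation_bias", mc_a = "minimal_contrast"),
    dplyr::select(tibble::as_tibble(b), "context",
      bias_b = "mutation_bias", mc_b = "minimal_contrast"),
    by = "context"
  )
  out <- dplyr::mutate(
    out,
    bias_diff = .data$bias_a - .data$bias_b,
    mc_diff = .data$mc_a - .data$mc_b,
    defined = !is.na(.data$bias_diff) & !is.na(.data$mc_diff)
  )
  dplyr::arrange(out, dplyr::desc(abs(.data$bias_diff)))
}

#' Plot-ready bias vs minimal-contrast table
#'
#' One record per context with a defined mutation bias and minimal
#' contrast, plus a complement-pair identifier shared by each context and
#' its reverse complement, so that the expected pairing of complementary
#' contexts ("dots in pairs") is directly inspectable.
#'
#' @param stats A `ctxmut_stats` table from [context_statistics()].
#' @return A tibble: `context`, `mutation_bias`, `minimal_contrast`,
#'   `pair_id`, `n`.
#' @export
scatter_data <- function(stats) {
  out <- dplyr::filter(tibble::as_tibble(stats),
    !is.na(.data$mutation_bias), !is.na(.data$minimal_contrast))
  rc <- reverse_complement_context(out$context)
  dplyr::select(
    dplyr::mutate(out, pair_id = pmin(.data$context, rc)),
    "context", "mutation_bias", "minimal_contrast", "pair_id", "n"
  )
}

#' Packaged reference tables of published values
#'
#' Small plain-text tables transcribed from published comparative work,
#' shipped for use as the second species in [compare_stats()]-style reports
#' and for spectrum/composition cross-checks:
#' `"spectrum"` — the printed single-nucleotide mutation-spectrum fractions
#' for D. melanogaster and H. sapiens; `"composition"` — printed fly
#' nucleotide composition of complete alignments vs conserved regions;
#' `"representation"` — printed word over/under-representation scores (C,
#' percent) for both species; `"human_contexts"` — the contexts reported as
#' hypermutable in the human germline (qualitative; the underlying
#' per-context human table is external and is consumed, never recomputed).
#'
#' @param name Which table to load.
#' @return A tibble.
#' @export
reference_table <- function(name = c("spectrum", "composition", "representation",
                                     "human_contexts")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, "_reference.tsv"),
    package = "contextmut", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, comment = "#")
}

#' Write / read pipeline tables
#'
#' Thin TSV round-trip helpers for the pipeline's tabular outputs (events,
#' word frequencies, context statistics, comparisons).
#'
#' @param x A tibble.
#' @param path File path.
#' @export
write_ctxmut_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}

#' @rdname write_ctxmut_tsv
#' @export
read_ctxmut_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
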