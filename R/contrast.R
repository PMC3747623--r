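#' Count mutation events per context
#'
#' Each called event carries its ancestral base and the three ancestral
#' bases on either side, i.e. an ancestral 7-mer with the mutated base in
#' the middle. The event increments the count `N` of every context
#' `{b>d | pos, W}` whose word `W` is a contiguous window of that 7-mer
#' containing the central base (at offset `pos`), once per context: one
#' window of length 1, two of length 2, three of length 3 and four of
#' length 4 — ten contexts per event when `min_len = 1, max_len = 4`.
#'
#' @param events Event tibble from [call_mutations()] (needs `ancestral`,
#'   `derived`, `left_flank`, `right_flank`).
#' @param min_len,max_len Context word lengths to count (1-4).
#' @return A tibble: the [enumerate_contexts()] table plus a column `n`.
#'   Counts are monotone: a context never exceeds any of its subcontexts.
#' @export
count_contexts <- function(events, min_len = 1L, max_len = 4L) {
  universe <- enumerate_contexts(min_len, max_len)
  if (nrow(events) == 0) {
    return(dplyr::mutate(universe, n = 0L))
  }
  seven <- paste0(events$left_flank, events$ancestral, events$right_flank)
  hits <- purrr::map_dfr(seq(min_len, max_len), function(k) {
    purrr::map_dfr(seq(5L - k, 4L), function(s) {
      tibble::tibble(
        word = substr(seven, s, s + k - 1L),
        pos = 4L - s + 1L,
        derived = events$derived
      )
    })
  })
  hits <- dplyr::count(hits, .data$word, .data$pos, .data$derived, name = "n")
  out <- dplyr::left_join(universe, hits, by = c("word", "pos", "derived"))
  dplyr::mutate(out, n = dplyr::coalesce(.data$n, 0L))
}

contrast_value <- function(n_ctx, p_w, n_sub, p_sub) {
  bad <- !is.na(p_w) & p_w == 0 & n_ctx > 0
  if (any(bad, na.rm = TRUE)) {
    abort_ctx("data inconsistency: context word has zero frequency but nonzero mutation count")
  }
  ifelse(
    is.na(n_sub) | is.na(p_sub) | n_sub == 0 | p_sub == 0 | is.na(p_w),
    NA_real_,
    (n_ctx / p_w) / (n_sub / p_sub)
  )
}

#' Contrast between a context and one of its subcontexts
#'
#' The contrast of a context and a subcontext is the ratio of their
#' conditional mutation probabilities, estimated as
#' `(N_ctx / P_W) / (N_sub / P_W')`, where `N` are observed mutation counts
#' and `P` the word frequencies among words of the same length. A value
#' above 1 means the mutation rate in the full context exceeds the rate in
#' the subcontext; below 1, a depressed rate. Undefined ratios
#' (`N_sub = 0` or `P_W' = 0`) are returned as `NA`, distinct from an
#' observed zero.
#'
#' @param ctx,sub Context strings; `sub` must be a subcontext of `ctx` (or
#'   equal to it, giving 1).
#' @param counts Context counts from [count_contexts()].
#' @param freqs Word-frequency table from [count_words()] /
#'   [conserved_words()] — conventionally the conserved-region table.
#' @return A single numeric contrast.
#' @export
contrast <- function(ctx, sub, counts, freqs) {
  pc <- parse_context(ctx)
  ps <- parse_context(sub)
  if (ctx != sub) {
    subs <- subcontext_pairs(pc)
    if (!sub %in% subs$sub_context) abort_ctx("'%s' is not a subcontext of '%s'", sub, ctx)
  }
  n <- stats::setNames(counts$n, counts$context)
  contrast_value(
    n[[ctx]], word_frequency(freqs, pc$word),
    n[[sub]], word_frequency(freqs, ps$word)
  )
}

#' @rdname contrast
#' @export
mutation_bias <- function(ctx, counts, freqs) {
  pc <- parse_context(ctx)
  base_ctx <- format_context(pc$ancestral, 1L, pc$derived)
  if (ctx == base_ctx) return(1)
  contrast(ctx, base_ctx, counts, freqs)
}

#' @rdname contrast
#' @return `minimal_contrast()`: a one-row tibble with `minimal_contrast`
#'   (the defined subcontext contrast closest to 1; `NA` if none is defined)
#'   and `argmin_subcontext`. Ties on `|value - 1|` break to the shorter
#'   subcontext word, then lexicographic word, then smaller position.
#' @export
minimal_contrast <- function(ctx, counts, freqs) {
  subs <- subcontext_pairs(parse_context(ctx))
  if (nrow(subs) == 0) abort_ctx("'%s' has no proper subcontext", ctx)
  vals <- vapply(subs$sub_context, function(s) contrast(ctx, s, counts, freqs),
    numeric(1), USE.NAMES = FALSE)
  defined <- which(!is.na(vals))
  if (length(defined) == 0) {
    return(tibble::tibble(minimal_contrast = NA_real_, argmin_subcontext = NA_character_))
  }
  best <- defined[order(abs(vals[defined] - 1), subs$sub_length[defined],
    subs$sub_word[defined], subs$sub_pos[defined])][1]
  tibble::tibble(minimal_contrast = vals[best], argmin_subcontext = subs$sub_context[best])
}

#' Context statistics: mutation bias and minimal contrast for every context
#'
#' For each enumerated context this computes the contrast against every
#' proper subcontext, the mutation bias (the contrast against the unique
#' length-1 subcontext — the total excess or deficiency of the mutation in
#' the context), and the minimal contrast (the subcontext contrast whose
#' value is closest to 1 — the excess not explained by any subcontext).
#' Ties on `|contrast - 1|` break deterministically: shorter subcontext word
#' first, then lexicographic word, then smaller position. Undefined
#' contrasts (zero subcontext count or frequency) are flagged and excluded
#' from the minimal-contrast search.
#'
#' @param events Event tibble from [call_mutations()], or a precomputed
#'   count table from [count_contexts()] covering lengths 1..`max_len`.
#' @param freqs Word-frequency table (conventionally conserved-region
#'   frequencies, see [conserved_words()]).
#' @param min_len,max_len Context word lengths reported (default 2-4; the
#'   length-1 counts are always used as bias denominators).
#' @return A tibble of class `ctxmut_stats`: `context`, `word`, `pos`,
#'   `ancestral`, `derived`, `length`, `n`, `mutation_bias`,
#'   `minimal_contrast`, `argmin_subcontext`, `n_subcontexts_defined`,
#'   `flag` (`"ok"`, `"undefined_bias"`, `"undefined_minimal_contrast"`).
#'   The full (context, subcontext, contrast) table is attached as
#'   attribute `"contrasts"` and returned by [subcontext_contrasts()].
#' @export
context_statistics <- function(events, freqs, min_len = 2L, max_len = 4L) {
  counts <- if (all(c("context", "n") %in% names(events))) {
    events
  } else {
    count_contexts(events, 1L, max_len)
  }
  if (!all(enumerate_contexts(1L, 1L)$context %in% counts$context)) {
    abort_ctx("counts must include length-1 contexts (bias denominators)")
  }
  universe <- dplyr::filter(counts, .data$length >= min_len, .data$length <= max_len)
  pairs <- subcontext_contrasts(counts, freqs, min_len = min_len, max_len = max_len)
  bias <- dplyr::select(
    dplyr::filter(pairs, .data$sub_length == 1L),
    "context", mutation_bias = "contrast"
  )
  minimal <- dplyr::slice_head(
    dplyr::group_by(
      dplyr::arrange(
        dplyr::filter(pairs, !is.na(.data$contrast)),
        .data$context, abs(.data$contrast - 1),
        .data$sub_length, .data$sub_word, .data$sub_pos
      ),
      .data$context
    ),
    n = 1
  )
  minimal <- dplyr::select(dplyr::ungroup(minimal),
    "context", minimal_contrast = "contrast", argmin_subcontext = "sub_context")
  n_def <- dplyr::summarise(
    dplyr::group_by(pairs, .data$context),
    n_subcontexts_defined = sum(!is.na(.data$contrast)),
    .groups = "drop"
  )
  out <- dplyr::left_join(universe, bias, by = "context")
  out <- dplyr::left_join(out, minimal, by = "context")
  out <- dplyr::left_join(out, n_def, by = "context")
  out <- dplyr::mutate(
    out,
    n_subcontexts_defined = dplyr::coalesce(.data$n_subcontexts_defined, 0L),
    flag = dplyr::case_when(
      is.na(.data$minimal_contrast) ~ "undefined_minimal_contrast",
      is.na(.data$mutation_bias) ~ "undefined_bias",
      TRUE ~ "ok"
    )
  )
  attr(out, "contrasts") <- pairs
  class(out) <- c("ctxmut_stats", class(out))
  out
}

#' @rdname context_statistics
#' @param counts A count table from [count_contexts()].
#' @export
subcontext_contrasts <- function(counts, freqs, min_len = 2L, max_len = 4L) {
  parents <- dplyr::filter(counts, .data$length >= min_len, .data$length <= max_len)
  pairs <- subcontext_pairs(parents)
  pairs <- dplyr::left_join(pairs, dplyr::select(parents, "context", "word"), by = "context")
  n_lookup <- stats::setNames(counts$n, counts$context)
  pairs <- dplyr::mutate(
    pairs,
    n_ctx = unname(n_lookup[.data$context]),
    n_sub = unname(n_lookup[.data$sub_context]),
    p_word = word_frequency(freqs, .data$word),
    p_sub_word = word_frequency(freqs, .data$sub_word),
    contrast = contrast_value(.data$n_ctx, .data$p_word, .data$n_sub, .data$p_sub_word)
  )
  dplyr::select(pairs, "context", "sub_context", "sub_word", "sub_pos",
    "sub_length", "n_ctx", "n_sub", "contrast")
}

#' Single-nucleotide mutation spectrum
#'
#' Tabulates the twelve directed substitutions over a set of events and
#' reports the fraction of each, classified as transition or transversion,
#' sorted by increasing fraction (the layout used for cross-species spectrum
#' comparisons). `glance()` on the result gives the transition and
#' transversion totals and their ratio.
#'
#' @param events Event tibble with `ancestral` and `derived` columns.
#' @return A tibble of class `ctxmut_spectrum`: `substitution`, `ancestral`,
#'   `derived`, `class`, `n`, `fraction`.
#' @export
spectrum_table <- function(events) {
  if (nrow(events) == 0) abort_ctx("spectrum requires at least one event")
  subs <- substitutions()
  obs <- dplyr::count(events, .data$ancestral, .data$derived)
  out <- dplyr::left_join(subs, obs, by = c("ancestral", "derived"))
  out <- dplyr::mutate(
    out,
    n = dplyr::coalesce(.data$n, 0L),
    fraction = .data$n / sum(.data$n)
  )
  out <- dplyr::arrange(out, .data$fraction, .data$substitution)
  class(out) <- c("ctxmut_spectrum", class(out))
  out
}
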