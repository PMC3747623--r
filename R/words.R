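all_words <- function(k) {
  sort(apply(
    as.matrix(expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE)),
    1, paste0, collapse = ""
  ))
}

#' Count 1-4 bp word occurrences and within-length frequencies
#'
#' Counts every overlapping k-word (sliding window, step 1) for k up to
#' `max_k` over one or more DNA sequences, and normalizes counts to
#' frequencies `P_W` among all words of the same length. A window is counted
#' only when all its symbols are in ACGT; gaps and ambiguity codes break the
#' window. When counting conserved regions, pass the run strings (words
#' never span a break between conserved runs) — [conserved_words()] does
#' this directly from a mask.
#'
#' @param seqs Character vector of DNA sequences (uppercased internally).
#' @param max_k Maximum word length, at most 4.
#' @param provenance Label recorded with the table, e.g. `"complete"` or
#'   `"conserved"`.
#' @return A tibble of class `ctxmut_words` with one row per word of each
#'   length 1..`max_k` (zero counts included): `k`, `word`, `count`, `total`
#'   (all k-word windows counted), `frequency` (`count / total`) and
#'   `provenance`.
#' @examples
#' count_words("ACGT", max_k = 2)
#' @export
count_words <- function(seqs, max_k = 4L, provenance = "sequence") {
  if (max_k < 1 || max_k > 4) abort_ctx("max_k must be between 1 and 4")
  seqs <- toupper(seqs)
  seqs <- seqs[nchar(seqs) > 0]
  set <- Biostrings::DNAStringSet(if (length(seqs)) seqs else character(0))
  out <- purrr::map_dfr(seq_len(max_k), function(k) {
    counts <- if (length(set)) {
      colSums(Biostrings::oligonucleotideFrequency(set, width = k))
    } else {
      stats::setNames(rep(0, 4^k), all_words(k))
    }
    tibble::tibble(k = k, word = names(counts), count = as.numeric(counts))
  })
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$k),
    total = sum(.data$count),
    frequency = dplyr::if_else(.data$total > 0, .data$count / .data$total, NA_real_)
  )
  out <- dplyr::ungroup(dplyr::mutate(out, provenance = provenance))
  class(out) <- c("ctxmut_words", class(out))
  out
}

#' @rdname count_words
#' @param mask A conserved mask from [conserved_mask()].
#' @export
conserved_words <- function(mask, max_k = 4L) {
  runs <- dplyr::summarise(
    dplyr::group_by(mask, .data$run),
    seq = paste0(.data$base[order(.data$col)], collapse = ""),
    .groups = "drop"
  )
  count_words(runs$seq, max_k = max_k, provenance = "conserved")
}

#' Look up word frequencies and frequency ratios
#'
#' `word_frequency()` returns `P_W` for each word (frequency among all words
#' of its own length). `frequency_ratio()` returns `P_W / P_W'`, the
#' denominator structure of the contrast estimator: with `W'` a subword of
#' `W`, the ratio estimates the probability that an occurrence of `W'`
#' extends to `W`.
#'
#' @param table A `ctxmut_words` table from [count_words()].
#' @param word,word_sub Words to look up (vectorized).
#' @return `word_frequency()`: numeric vector of frequencies.
#'   `frequency_ratio()`: numeric vector; `NA` (undefined, distinct from
#'   zero) when `P_W'` is zero; `0` when `W` is unobserved but `W'` is.
#' @export
word_frequency <- function(table, word) {
  key <- paste0(nchar(table$word), ".", table$word)
  table$frequency[match(paste0(nchar(word), ".", word), key)]
}

#' @rdname word_frequency
#' @export
frequency_ratio <- function(table, word, word_sub) {
  p <- word_frequency(table, word)
  ps <- word_frequency(table, word_sub)
  out <- ifelse(!is.na(ps) & ps > 0, p / ps, NA_real_)
  out
}
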