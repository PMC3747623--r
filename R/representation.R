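#' Expected word frequency from subword frequencies
#'
#' Maximal-order Markov expectation for a k-word built from the observed
#' frequencies of its length-(k-1) and length-(k-2) subwords:
#' `Exp(W) = P(prefix) * P(suffix) / P(middle)`, with the middle frequency
#' of the empty word defined as 1, so that for k = 2 the expectation
#' reduces to the independence product of the two single-base frequencies.
#'
#' @param word Character vector of words, each 2-4 bp.
#' @param table A word-frequency table from [count_words()].
#' @return Numeric vector of expected frequencies; `NA` when a required
#'   subword frequency is zero or missing.
#' @export
expected_frequency <- function(word, table) {
  k <- nchar(word)
  if (any(k < 2 | k > 4)) abort_ctx("expected frequencies are defined for 2-4 bp words")
  prefix <- substr(word, 1, k - 1)
  suffix <- substr(word, 2, k)
  p_pre <- word_frequency(table, prefix)
  p_suf <- word_frequency(table, suffix)
  p_mid <- ifelse(k == 2, 1, word_frequency(table, substr(word, 2, k - 1)))
  ifelse(
    is.na(p_pre) | is.na(p_suf) | is.na(p_mid) | p_mid == 0 | p_pre == 0 | p_suf == 0,
    NA_real_,
    p_pre * p_suf / p_mid
  )
}

#' Genomic word over/under-representation score
#'
#' Scores each word by its percent deviation from the subword-based Markov
#' expectation: `C = (Obs(W) - Exp(W)) / Exp(W) * 100`, in percent. Positive
#' scores mean over-representation. The score depends only on frequencies,
#' so it is invariant under duplicating the input sequence.
#'
#' @param word Character vector of 2-4 bp words.
#' @param table A word-frequency table from [count_words()].
#' @return A tibble of class `ctxmut_repr`: `word`, `obs_freq`, `exp_freq`,
#'   `c_percent`.
#' @examples
#' tab <- count_words(paste(rep("CCA", 50), collapse = ""))
#' representation_score("CCA", tab)
#' @export
representation_score <- function(word, table) {
  obs <- word_frequency(table, word)
  expd <- expected_frequency(word, table)
  out <- tibble::tibble(
    word = word,
    obs_freq = obs,
    exp_freq = expd,
    c_percent = (obs - expd) / expd * 100
  )
  class(out) <- c("ctxmut_repr", class(out))
  out
}
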