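#' The twelve directed single-nucleotide substitutions
#'
#' Every directed change between two distinct bases, classified as a
#' transition (purine<->purine or pyrimidine<->pyrimidine) or a
#' transversion.
#'
#' @return A tibble with columns `substitution` (e.g. `"C>T"`), `ancestral`,
#'   `derived` and `class` (`"transition"` or `"transversion"`).
#' @examples
#' substitutions()
#' @export
substitutions <- function() {
  grid <- tidyr::expand_grid(ancestral = DNA_BASES, derived = DNA_BASES)
  grid <- dplyr::filter(grid, .data$ancestral != .data$derived)
  dplyr::mutate(
    grid,
    substitution = paste0(.data$ancestral, ">", .data$derived),
    class = dplyr::if_else(is_transition(.data$ancestral, .data$derived),
      "transition", "transversion"
    ),
    .before = 1
  )
}

#' @rdname substitutions
#' @param ancestral,derived Vectors of single bases in `A`, `C`, `G`, `T`.
#' @export
is_transition <- function(ancestral, derived) {
  purine <- c("A", "G")
  (ancestral %in% purine) == (derived %in% purine) & ancestral != derived
}

#' Render mutation contexts in canonical string form
#'
#' A mutation context is a triple: a word over ACGT of length 1-4, a 1-based
#' position in the word, and a derived base replacing the word's base at that
#' position. The canonical rendering is `"{C>T|1,CG}"`, read as "a C>T
#' mutation in the first position of the word CG".
#'
#' @param word Character vector of ACGT words, 1-4 bp.
#' @param pos Integer vector of 1-based positions within `word`.
#' @param derived Character vector of derived bases.
#' @return A character vector of canonical context strings.
#' @examples
#' format_context("CG", 1, "T")
#' @export
format_context <- function(word, pos, derived) {
  anc <- substr(word, pos, pos)
  bad <- anc == derived
  if (any(bad)) {
    abort_ctx("derived base must differ from the word's base at `pos` (e.g. %s)",
      paste0(word[bad][1], "[", pos[bad][1], "]"))
  }
  paste0("{", anc, ">", derived, "|", pos, ",", word, "}")
}

#' Parse canonical context strings
#'
#' @param x Character vector of context strings such as `"{C>T|1,CG}"`.
#' @return A tibble with columns `context`, `word`, `pos`, `ancestral`,
#'   `derived` and `length`.
#' @examples
#' parse_context("{C>T|2,ACG}")
#' @export
parse_context <- function(x) {
  m <- stringr::str_match(x, "^\\{([ACGT])>([ACGT])\\|([1-4]),([ACGT]{1,4})\\}$")
  if (anyNA(m[, 1])) {
    abort_ctx("not a valid context string: '%s'", x[is.na(m[, 1])][1])
  }
  out <- tibble::tibble(
    context = x,
    word = m[, 5],
    pos = as.integer(m[, 4]),
    ancestral = m[, 2],
    derived = m[, 3],
    length = nchar(m[, 5])
  )
  if (any(out$ancestral == out$derived)) {
    abort_ctx("not a valid context string (ancestral equals derived): '%s'",
      x[out$ancestral == out$derived][1])
  }
  if (any(out$pos > out$length)) {
    abort_ctx("context position exceeds word length: '%s'", x[out$pos > out$length][1])
  }
  if (any(substr(out$word, out$pos, out$pos) != out$ancestral)) {
    bad <- substr(out$word, out$pos, out$pos) != out$ancestral
    abort_ctx("word base at `pos` disagrees with the stated ancestral base: '%s'", x[bad][1])
  }
  out
}

#' Enumerate all mutation contexts of given word lengths
#'
#' Generates every (word, position, derived base) triple with word lengths in
#' `[min_len, max_len]`, in a fixed deterministic order: by word length, then
#' word (lexicographic), then position, then derived base (lexicographic).
#' There are 12 length-1 contexts, 96 of length 2, 576 of length 3 and 3072
#' of length 4 (3744 in the full 2-4 bp set).
#'
#' @param min_len,max_len Word length bounds, between 1 and 4.
#' @return A tibble with columns `context`, `word`, `pos`, `ancestral`,
#'   `derived`, `length`.
#' @examples
#' enumerate_contexts(2, 2)
#' @export
enumerate_contexts <- function(min_len = 2L, max_len = 4L) {
  if (min_len < 1 || max_len > 4 || min_len > max_len) {
    abort_ctx("word lengths must satisfy 1 <= min_len <= max_len <= 4")
  }
  per_len <- function(k) {
    words <- sort(apply(
      as.matrix(expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE)),
      1, paste0, collapse = ""
    ))
    grid <- tidyr::expand_grid(word = words, pos = seq_len(k), derived = DNA_BASES)
    grid <- dplyr::mutate(grid, ancestral = substr(.data$word, .data$pos, .data$pos))
    dplyr::filter(grid, .data$ancestral != .data$derived)
  }
  out <- purrr::map_dfr(seq(min_len, max_len), per_len)
  out <- dplyr::mutate(out,
    length = nchar(.data$word),
    context = format_context(.data$word, .data$pos, .data$derived)
  )
  dplyr::arrange(
    dplyr::select(out, "context", "word", "pos", "ancestral", "derived", "length"),
    .data$length, .data$word, .data$pos, .data$derived
  )
}

#' Proper subcontexts of a mutation context
#'
#' A context `{mut|pos',W'}` is a subcontext of `{mut|pos,W}` when `W'` is a
#' contiguous subword of `W` containing position `pos` (remapped to `pos'`)
#' with the same substitution: every mutation matching the context also
#' matches the subcontext. `subcontexts()` returns all proper subcontexts of
#' one context; `subcontext_pairs()` vectorizes over many contexts and
#' returns a parent/sub long table. Discontiguous subwords (e.g. CNG) are
#' not part of the relation.
#'
#' @param ctx A single context string or one-row tibble from
#'   [parse_context()].
#' @return For `subcontexts()`, a tibble of contexts (possibly empty, for
#'   length-1 contexts). For `subcontext_pairs()`, a tibble with the parent
#'   `context` plus `sub_context`, `sub_word`, `sub_pos`, `sub_length`.
#' @examples
#' subcontexts("{C>T|2,ACG}")
#' @export
subcontexts <- function(ctx) {
  if (is.character(ctx)) ctx <- parse_context(ctx)
  stopifnot(nrow(ctx) == 1)
  pairs <- subcontext_pairs(ctx)
  parse_context(pairs$sub_context)
}

#' @rdname subcontexts
#' @param contexts A tibble of contexts (from [parse_context()] or
#'   [enumerate_contexts()]) or a character vector of context strings.
#' @export
subcontext_pairs <- function(contexts) {
  if (is.character(contexts)) contexts <- parse_context(contexts)
  spans <- tidyr::expand_grid(s = 1:4, e = 1:4)
  spans <- dplyr::filter(spans, .data$e >= .data$s)
  out <- tidyr::crossing(
    dplyr::select(contexts, "context", "word", "pos", "derived", "length"),
    spans
  )
  out <- dplyr::filter(
    out,
    .data$e <= .data$length,
    .data$e - .data$s + 1L < .data$length, # proper
    .data$s <= .data$pos, .data$pos <= .data$e
  )
  out <- dplyr::mutate(
    out,
    sub_word = substr(.data$word, .data$s, .data$e),
    sub_pos = .data$pos - .data$s + 1L,
    sub_length = .data$e - .data$s + 1L,
    sub_context = format_context(.data$sub_word, .data$sub_pos, .data$derived)
  )
  dplyr::select(
    dplyr::arrange(out, .data$context, .data$sub_length, .data$sub_word, .data$sub_pos),
    "context", "sub_context", "sub_word", "sub_pos", "sub_length"
  )
}

#' Reverse-complement a mutation context
#'
#' Maps a context to its opposite-strand equivalent: the word is
#' reverse-complemented, the position becomes `length - pos + 1`, and both
#' ancestral and derived bases are complemented. The operation is an
#' involution. Complementary contexts are expected to show similar mutation
#' statistics on strand-symmetric data, but are always reported separately.
#'
#' @param ctx A character vector of context strings, or a context tibble.
#' @return Same type as the input (strings in, strings out).
#' @examples
#' reverse_complement_context("{C>T|1,CG}")
#' @export
reverse_complement_context <- function(ctx) {
  strings_in <- is.character(ctx)
  if (strings_in) ctx <- parse_context(ctx)
  out <- dplyr::mutate(
    ctx,
    word = revcomp_string(.data$word),
    pos = .data$length - .data$pos + 1L,
    ancestral = unname(DNA_COMPLEMENT[.data$ancestral]),
    derived = unname(DNA_COMPLEMENT[.data$derived]),
    context = format_context(.data$word, .data$pos, .data$derived)
  )
  if (strings_in) out$context else out
}
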