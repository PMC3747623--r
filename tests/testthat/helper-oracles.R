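# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

# all proper contiguous subwords of `word` containing index `pos`
oracle_subcontexts <- function(word, pos, derived) {
  k <- nchar(word)
  out <- character(0)
  for (s in seq_len(k)) {
    for (e in s:k) {
      if (e - s + 1 < k && s <= pos && pos <= e) {
        out <- c(out, format_context(substr(word, s, e), pos - s + 1L, derived))
      }
    }
  }
  sort(unique(out))
}

# per-event, per-window recount of context hits
oracle_count_contexts <- function(events, min_len = 1, max_len = 4) {
  acc <- list()
  for (i in seq_len(nrow(events))) {
    seven <- paste0(events$left_flank[i], events$ancestral[i], events$right_flank[i])
    for (k in min_len:max_len) {
      for (s in 1:(7 - k + 1)) {
        e <- s + k - 1
        if (s <= 4 && 4 <= e) {
          ctx <- format_context(substr(seven, s, e), 4L - s + 1L, events$derived[i])
          acc[[ctx]] <- (if (is.null(acc[[ctx]])) 0L else acc[[ctx]]) + 1L
        }
      }
    }
  }
  tibble::tibble(context = names(acc), n = unlist(acc, use.names = FALSE))
}

# random flanked events with uniform 7-mers
random_events <- function(n) {
  bases <- c("A", "C", "G", "T")
  seven <- replicate(n, paste0(sample(bases, 7, replace = TRUE), collapse = ""))
  anc <- substr(seven, 4, 4)
  derived <- vapply(anc, function(b) sample(setdiff(bases, b), 1), character(1))
  tibble::tibble(
    chrom = "chr", pos0 = seq_len(n) - 1L,
    ancestral = anc, derived = unname(derived),
    left_flank = substr(seven, 1, 3), right_flank = substr(seven, 5, 7),
    derived_count = 1L
  )
}

# naive per-column re-check of the four calling conditions
oracle_check_event <- function(block, roster, col) {
  m <- do.call(rbind, strsplit(toupper(unname(block$text)), ""))
  rownames(m) <- names(block$text)
  bases <- c("A", "C", "G", "T")
  og <- m[roster$outgroups, col]
  if (length(unique(og)) != 1 || !og[1] %in% bases) return(FALSE) # condition 1
  anc <- og[[1]]
  fo <- m[roster$focal, col]
  if (!all(fo %in% bases)) return(FALSE)
  if (length(unique(fo)) != 2) return(FALSE) # condition 3
  if (!anc %in% fo || all(fo == anc)) return(FALSE) # condition 2
  flank_cols <- c(col - 3:1, col + 1:3)
  if (any(flank_cols < 1 | flank_cols > ncol(m))) return(FALSE)
  for (fc in flank_cols) { # condition 4
    column <- m[c(roster$focal, roster$outgroups), fc]
    if (length(unique(column)) != 1 || !column[1] %in% bases) return(FALSE)
  }
  TRUE
}

# naive overlapping k-mer scan
oracle_count_kmers <- function(seqs, k) {
  acc <- list()
  for (s in seqs) {
    chars <- strsplit(toupper(s), "")[[1]]
    if (length(chars) < k) next
    for (i in 1:(length(chars) - k + 1)) {
      w <- paste0(chars[i:(i + k - 1)], collapse = "")
      if (grepl("^[ACGT]+$", w)) {
        acc[[w]] <- (if (is.null(acc[[w]])) 0L else acc[[w]]) + 1L
      }
    }
  }
  acc
}

make_freq_table <- function(freqs) {
  tibble::tibble(
    k = nchar(names(freqs)), word = names(freqs),
    count = NA_real_, total = NA_real_, frequency = unname(freqs),
    provenance = "manual"
  )
}

make_counts <- function(n) {
  meta <- parse_context(names(n))
  dplyr::mutate(meta, n = unname(n))
}

quiet_sim <- function(...) simulate_population(sim_config(...))
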