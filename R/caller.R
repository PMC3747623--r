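CODE_LEVELS <- c("A", "C", "G", "T", "-")

# per-column counts of each symbol class over a character matrix
column_base_counts <- function(m) {
  n <- ncol(m)
  counts <- matrix(0L, nrow = 6, ncol = n,
    dimnames = list(c(CODE_LEVELS, "other"), NULL))
  if (nrow(m) == 0) return(counts)
  for (i in seq_along(CODE_LEVELS)) {
    counts[i, ] <- colSums(m == CODE_LEVELS[i])
  }
  counts["other", ] <- nrow(m) - colSums(counts[1:5, , drop = FALSE])
  counts
}

# base shared by all rows at each column, NA where rows differ / gap / non-ACGT
monomorphic_base <- function(counts, n_rows) {
  hit <- counts[1:4, , drop = FALSE] == n_rows
  idx <- apply(hit, 2, function(z) if (any(z)) which(z)[1] else NA_integer_)
  DNA_BASES[idx]
}

block_call_data <- function(block, roster) {
  focal_present <- intersect(roster$focal, names(block$text))
  og_present <- intersect(roster$outgroups, names(block$text))
  fm <- block_matrix(block, focal_present)
  om <- block_matrix(block, og_present)
  list(
    focal = fm, outgroup = om,
    n_focal_present = length(focal_present),
    n_og_present = length(og_present),
    fcnt = column_base_counts(fm),
    ocnt = column_base_counts(om)
  )
}

#' Call polarized biallelic mutation events
#'
#' Scans every alignment column and emits one mutation event per column that
#' satisfies all four calling conditions:
#'
#' 1. every outgroup carries the same base `b` in ACGT (the ancestral base);
#' 2. among the focal genomes at least one carries `b` and at least one
#'    carries a different base;
#' 3. the focal genomes show exactly two distinct symbols, both in ACGT
#'    (any gap or ambiguity code in a focal row rejects the column);
#' 4. the three alignment columns immediately upstream and downstream are
#'    each monomorphic across every roster row (focal and outgroups), with a
#'    single ACGT base and no gaps — those six bases form the ancestral
#'    flanks.
#'
#' The event direction is ancestral `b` to the other focal allele. Columns
#' within three columns of a block edge cannot provide flanks and are never
#' called. Each variable column contributes exactly one event regardless of
#' how many genomes carry the derived allele (the derived-allele count is
#' recorded).
#'
#' @param blocks A list of `aln_block` objects, from [read_maf()],
#'   [read_aligned_fasta()] or [simulate_population()].
#' @param roster A [species_roster()].
#' @param min_focal_present Minimum number of focal genomes that must be
#'   present (as rows) in a block for its columns to be callable. Defaults to
#'   all focal genomes.
#' @param flank_scope Rows over which condition 4's monomorphism is checked:
#'   `"all"` (focal + outgroups, the default — the flank is the unambiguous
#'   ancestral context) or `"focal"`.
#' @return A tibble of events: `chrom`, `pos0` (0-based reference
#'   coordinate), `ancestral`, `derived`, `left_flank`, `right_flank`,
#'   `derived_count`.
#' @export
call_mutations <- function(blocks, roster, min_focal_present = NULL,
                           flank_scope = c("all", "focal")) {
  flank_scope <- match.arg(flank_scope)
  min_focal_present <- min_focal_present %||% length(roster$focal)
  purrr::map_dfr(blocks, function(block) {
    d <- block_call_data(block, roster)
    W <- block$width
    if (d$n_og_present < length(roster$outgroups) ||
      d$n_focal_present < min_focal_present || W < 7) {
      return(empty_events())
    }
    anc <- monomorphic_base(d$ocnt, d$n_og_present) # condition 1
    fc <- d$fcnt
    clean <- colSums(fc[5:6, , drop = FALSE]) == 0
    n_distinct <- colSums(fc[1:4, , drop = FALSE] > 0)
    anc_idx <- match(anc, DNA_BASES)
    anc_count <- ifelse(is.na(anc_idx), 0L,
      fc[1:4, , drop = FALSE][cbind(anc_idx, seq_len(W))])
    variable <- !is.na(anc) & clean & n_distinct == 2L & # conditions 2-3
      anc_count >= 1L & anc_count < d$n_focal_present
    # condition 4: flanks monomorphic over the chosen row scope
    mono_counts <- if (flank_scope == "all") {
      d$fcnt[1:4, , drop = FALSE] + d$ocnt[1:4, , drop = FALSE]
    } else {
      d$fcnt[1:4, , drop = FALSE]
    }
    mono_rows <- if (flank_scope == "all") d$n_focal_present + d$n_og_present else d$n_focal_present
    mono <- monomorphic_base(
      rbind(mono_counts, matrix(0L, 2, W)), mono_rows
    )
    is_mono <- !is.na(mono)
    flank_ok <- rep(FALSE, W)
    j <- seq_len(W)
    inner <- j[j >= 4 & j <= W - 3]
    if (length(inner) > 0) {
      flank_ok[inner] <-
        is_mono[inner - 3] & is_mono[inner - 2] & is_mono[inner - 1] &
        is_mono[inner + 1] & is_mono[inner + 2] & is_mono[inner + 3]
    }
    hit <- which(variable & flank_ok)
    if (length(hit) == 0) return(empty_events())
    derived <- vapply(hit, function(jj) {
      alleles <- DNA_BASES[fc[1:4, jj] > 0]
      setdiff(alleles, anc[jj])[[1]]
    }, character(1))
    pos0 <- ref_coordinates(block, roster$reference)
    tibble::tibble(
      chrom = block$chrom,
      pos0 = pos0[hit],
      ancestral = anc[hit],
      derived = derived,
      left_flank = vapply(hit, function(jj) paste0(mono[jj - 3:1], collapse = ""), character(1)),
      right_flank = vapply(hit, function(jj) paste0(mono[jj + 1:3], collapse = ""), character(1)),
      derived_count = as.integer(fc[1:4, , drop = FALSE][cbind(match(derived, DNA_BASES), hit)])
    )
  })
}

empty_events <- function() {
  tibble::tibble(
    chrom = character(0), pos0 = integer(0), ancestral = character(0),
    derived = character(0), left_flank = character(0),
    right_flank = character(0), derived_count = integer(0)
  )
}

#' Conserved-region mask
#'
#' Marks the alignment columns used for the conserved word-frequency
#' measure: all outgroups agree on an ACGT base `b` (the ancestral base), no
#' roster row carries a gap or non-ACGT symbol, and `b` matches at least one
#' focal variant at the column. The base recorded for word counting is the
#' ancestral base, so a clean biallelic column whose ancestral allele
#' segregates in the population is conserved.
#'
#' @inheritParams call_mutations
#' @return A tibble with one row per conserved column: `block`, `chrom`,
#'   `col` (1-based alignment column), `pos0` (reference coordinate, `NA` if
#'   the reference row is absent or gapped), `base` (ancestral base) and
#'   `run` (identifier of the maximal run of contiguous conserved columns;
#'   words never span run boundaries).
#' @export
conserved_mask <- function(blocks, roster) {
  run_offset <- 0L
  purrr::map_dfr(seq_along(blocks), function(bi) {
    block <- blocks[[bi]]
    d <- block_call_data(block, roster)
    if (d$n_og_present < length(roster$outgroups)) return(NULL)
    anc <- monomorphic_base(d$ocnt, d$n_og_present)
    no_bad <- colSums(d$fcnt[5:6, , drop = FALSE]) + colSums(d$ocnt[5:6, , drop = FALSE]) == 0
    anc_idx <- match(anc, DNA_BASES)
    W <- block$width
    anc_in_focal <- ifelse(is.na(anc_idx), FALSE,
      d$fcnt[1:4, , drop = FALSE][cbind(anc_idx, seq_len(W))] > 0)
    keep <- !is.na(anc) & no_bad & anc_in_focal &
      d$n_focal_present == length(roster$focal)
    cols <- which(keep)
    if (length(cols) == 0) return(NULL)
    run <- cumsum(c(TRUE, diff(cols) != 1L))
    pos0 <- ref_coordinates(block, roster$reference)
    tibble::tibble(
      chrom = block$chrom, block = bi, col = cols, pos0 = pos0[cols],
      base = anc[cols], run = paste0("b", bi, ".r", run)
    )
  })
}

#' Nucleotide composition: complete alignment vs conserved regions
#'
#' Compares the base composition of all alignment positions (every ACGT
#' symbol over every roster row) with the composition of the conserved
#' regions (ancestral base per conserved column), and reports the percent
#' difference of each base's fraction.
#'
#' @inheritParams call_mutations
#' @param mask A conserved mask from [conserved_mask()] computed on the same
#'   blocks; computed on the fly if omitted.
#' @return A tibble with `nucleotide`, `frac_all`, `frac_conserved` and
#'   `difference_pct` (rounded to one decimal for display, as
#'   `(frac_all - frac_conserved) / frac_all * 100`).
#' @export
composition_summary <- function(blocks, roster, mask = NULL) {
  mask <- mask %||% conserved_mask(blocks, roster)
  all_counts <- stats::setNames(rep(0, 4), DNA_BASES)
  for (block in blocks) {
    m <- block_matrix(block, c(roster$focal, roster$outgroups))
    cnt <- column_base_counts(m)
    all_counts <- all_counts + rowSums(cnt[1:4, , drop = FALSE])
  }
  cons_counts <- table(factor(mask$base, levels = DNA_BASES))
  frac_all <- as.numeric(all_counts) / sum(all_counts)
  frac_cons <- if (nrow(mask) > 0) as.numeric(cons_counts) / sum(cons_counts) else rep(NA_real_, 4)
  tibble::tibble(
    nucleotide = DNA_BASES,
    frac_all = frac_all,
    frac_conserved = frac_cons,
    difference_pct = composition_difference(frac_all, frac_cons)
  )
}

#' @rdname composition_summary
#' @param frac_all,frac_conserved Numeric vectors of base fractions.
#' @export
composition_difference <- function(frac_all, frac_conserved) {
  round((frac_all - frac_conserved) / frac_all * 100, 1)
}
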