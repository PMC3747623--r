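#' Simulation configuration for synthetic population alignments
#'
#' Bundles the parameters of the forward simulator: a single-generation
#' (star) population model in which each site of an ancestral sequence may
#' receive one biallelic derived allele shared by a uniformly drawn subset
#' of haplotypes. Context-dependent mutagenesis is planted through rate
#' multipliers attached to mutation contexts; at a site the longest planted
#' context matching the ancestral sequence wins, sites matching none mutate
#' at the base rate. Defaults mirror a fly-like resequencing panel: 37
#' focal haplotypes, 2 low-divergence outgroups, AT-rich base composition.
#'
#' @param genome_length Ancestral sequence length in bp.
#' @param base_composition Named probabilities for A, C, G, T (sums to 1).
#' @param n_focal Number of focal haplotypes.
#' @param n_outgroups Number of outgroup genomes.
#' @param base_rate Per-site probability of each specific substitution
#'   (expected events per site per substitution type, before multipliers).
#' @param multipliers Named numeric vector of planted rate multipliers, names
#'   are canonical context strings, e.g. `c("{C>T|1,CG}" = 8)`.
#' @param outgroup_divergence Per-site probability of a private substitution
#'   in each outgroup, placed at least 4 columns away from any planted event
#'   so polarization and flanks stay clean.
#' @param gap_rate Per-site probability of injecting a gap into one random
#'   row (disjoint from planted-event windows).
#' @param multiallelic_rate Per-site probability of injecting a third allele
#'   into the focal sample (disjoint from planted-event windows).
#' @param seed Integer seed; a fixed seed makes the emitted alignment
#'   byte-identical across runs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e5,
                       base_composition = c(A = 0.2979, C = 0.2022, G = 0.2021, T = 0.2978),
                       n_focal = 37L,
                       n_outgroups = 2L,
                       base_rate = 0.005,
                       multipliers = NULL,
                       outgroup_divergence = 0.02,
                       gap_rate = 0.002,
                       multiallelic_rate = 5e-4,
                       seed = NULL) {
  stopifnot(
    genome_length >= 20,
    abs(sum(base_composition) - 1) < 1e-6,
    n_focal >= 2, n_outgroups >= 2,
    base_rate >= 0, outgroup_divergence >= 0,
    gap_rate >= 0, multiallelic_rate >= 0
  )
  if (!is.null(multipliers)) {
    if (is.null(names(multipliers)) || any(multipliers <= 0)) {
      abort_ctx("multipliers must be a named numeric vector with positive values")
    }
    parse_context(names(multipliers)) # validates
  }
  structure(
    list(
      genome_length = as.integer(genome_length),
      base_composition = base_composition[DNA_BASES],
      n_focal = as.integer(n_focal), n_outgroups = as.integer(n_outgroups),
      base_rate = base_rate, multipliers = multipliers,
      outgroup_divergence = outgroup_divergence,
      gap_rate = gap_rate, multiallelic_rate = multiallelic_rate,
      seed = seed
    ),
    class = "sim_config"
  )
}

#' Simulate a population alignment with planted context-dependent rates
#'
#' Draws an ancestral sequence from the configured base composition, plants
#' biallelic derived alleles with per-site, per-substitution probability
#' `base_rate * multiplier(context)`, assigns each event to a uniformly
#' drawn derived-allele count in `1..n_focal-1`, and emits outgroups equal
#' to the ancestor apart from private divergence kept at least 4 columns
#' from every planted event. Planted events are spaced at least 4 columns
#' apart and kept at least 3 columns from the sequence ends, so each event
#' retains clean monomorphic flanks and a caller run on a noise-free
#' simulation recovers exactly the planted truth. Optional gap and
#' multiallelic noise exercises the calling filters without touching
#' planted-event windows.
#'
#' @param config A [sim_config()].
#' @return A list of class `ctxmut_sim` with elements `alignment` (a list of
#'   one `aln_block`; rows `focal_01..`, `outgroup_1..`), `roster`, `truth`
#'   (tibble: `pos0`, `ancestral`, `derived`, `derived_count`, `context` —
#'   the planted context matched, `NA` for base-rate events — and
#'   `multiplier`), `expected_bias` (planted contexts, multipliers, and the
#'   generator's true mutation bias for each: the multiplier divided by the
#'   mean multiplier over all sites of the context's ancestral base, since
#'   the length-1 bias denominator averages over hotspot and background
#'   sites alike) and `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$genome_length
  anc <- sample(DNA_BASES, L, replace = TRUE, prob = config$base_composition)
  anc_str <- paste0(anc, collapse = "")

  # per-site, per-derived-base rate matrix; planted contexts overwrite,
  # longest word last so the longest match wins
  rate <- matrix(0, nrow = L, ncol = 4, dimnames = list(NULL, DNA_BASES))
  ctx_id <- matrix(0L, nrow = L, ncol = 4)
  anc_idx <- match(anc, DNA_BASES)
  for (d in 1:4) rate[anc_idx != d, d] <- config$base_rate
  planted <- config$multipliers
  if (!is.null(planted)) {
    meta <- parse_context(names(planted))
    for (i in order(meta$length)) {
      m <- meta[i, ]
      w <- strsplit(m$word, "")[[1]]
      k <- length(w)
      ok <- rep(TRUE, L - k + 1L)
      for (j in seq_len(k)) ok <- ok & anc[j:(L - k + j)] == w[j]
      sites <- which(ok) + m$pos - 1L
      if (length(sites) > 0) {
        rate[cbind(sites, match(m$derived, DNA_BASES))] <- config$base_rate * planted[[i]]
        ctx_id[cbind(sites, match(m$derived, DNA_BASES))] <- i
      }
    }
  }
  rate[cbind(seq_len(L), anc_idx)] <- 0
  p_event <- pmin(rowSums(rate), 0.999)

  candidates <- which(stats::runif(L) < p_event)
  candidates <- candidates[candidates >= 4L & candidates <= L - 3L]
  keep <- logical(length(candidates))
  last <- -10L
  for (i in seq_along(candidates)) { # enforce >= 4 column spacing
    if (candidates[i] - last >= 4L) {
      keep[i] <- TRUE
      last <- candidates[i]
    }
  }
  sites <- candidates[keep]

  derived <- vapply(sites, function(s) {
    sample(DNA_BASES, 1, prob = rate[s, ] / sum(rate[s, ]))
  }, character(1))
  derived_count <- if (length(sites)) {
    sample(seq_len(config$n_focal - 1L), length(sites), replace = TRUE)
  } else {
    integer(0)
  }

  focal <- matrix(rep(anc, config$n_focal), nrow = config$n_focal, byrow = TRUE)
  for (i in seq_along(sites)) {
    rows <- sample.int(config$n_focal, derived_count[i])
    focal[rows, sites[i]] <- derived[i]
  }

  # noise sites must keep >= 4 columns from planted events (clean flanks)
  near_event <- rep(FALSE, L)
  for (s in sites) near_event[max(1, s - 3):min(L, s + 3)] <- TRUE
  allowed <- which(!near_event)

  outgroup <- matrix(rep(anc, config$n_outgroups), nrow = config$n_outgroups, byrow = TRUE)
  if (config$outgroup_divergence > 0 && length(allowed)) {
    for (o in seq_len(config$n_outgroups)) {
      div <- allowed[stats::runif(length(allowed)) < config$outgroup_divergence]
      if (length(div)) {
        outgroup[o, div] <- vapply(div, function(s) {
          sample(setdiff(DNA_BASES, anc[s]), 1)
        }, character(1))
      }
    }
  }

  n_rows <- config$n_focal + config$n_outgroups
  if (config$gap_rate > 0 && length(allowed)) {
    gaps <- allowed[stats::runif(length(allowed)) < config$gap_rate]
    for (s in gaps) {
      # never gap the first focal row: it is the coordinate reference and the
      # simulated alignment has no true indels
      r <- sample(2:n_rows, 1)
      if (r <= config$n_focal) focal[r, s] <- "-" else outgroup[r - config$n_focal, s] <- "-"
    }
  }
  if (config$multiallelic_rate > 0 && length(allowed)) {
    tri <- allowed[stats::runif(length(allowed)) < config$multiallelic_rate]
    for (s in tri) {
      alts <- sample(setdiff(DNA_BASES, anc[s]), 2)
      rows <- sample.int(config$n_focal, 2)
      focal[rows[1], s] <- alts[1]
      focal[rows[2], s] <- alts[2]
    }
  }

  focal_names <- sprintf("focal_%02d", seq_len(config$n_focal))
  og_names <- sprintf("outgroup_%d", seq_len(config$n_outgroups))
  text <- c(
    stats::setNames(apply(focal, 1, paste0, collapse = ""), focal_names),
    stats::setNames(apply(outgroup, 1, paste0, collapse = ""), og_names)
  )
  id <- if (length(sites)) ctx_id[cbind(sites, match(derived, DNA_BASES))] else integer(0)
  truth <- tibble::tibble(
    pos0 = sites - 1L,
    ancestral = anc[sites],
    derived = derived,
    derived_count = derived_count,
    context = if (is.null(planted)) NA_character_ else
      ifelse(id > 0, names(planted)[pmax(id, 1L)], NA_character_),
    multiplier = if (is.null(planted)) 1 else
      ifelse(id > 0, unname(planted)[pmax(id, 1L)], 1)
  )
  structure(
    list(
      alignment = list(new_block(text, 0L, "sim", id = 1L)),
      roster = species_roster(focal_names, og_names),
      truth = truth,
      expected_bias = expected_bias_table(planted, anc, rate, config),
      ancestor = anc_str,
      config = config
    ),
    class = "ctxmut_sim"
  )
}

# True mutation bias of each planted context under the generator's model.
# The length-1 bias denominator averages over ALL ancestral-base sites,
# hotspots included, so the true bias of a multiplier-m context is m divided
# by the mean multiplier over sites of its ancestral base (for that derived
# base), times the word-count edge factor (L-k+1)/L. Only in the limit of a
# vanishingly rare context word does this reduce to the raw multiplier.
expected_bias_table <- function(planted, anc, rate, config) {
  if (is.null(planted)) {
    return(tibble::tibble(context = character(0), multiplier = numeric(0),
      expected_bias = numeric(0)))
  }
  meta <- parse_context(names(planted))
  L <- length(anc)
  eb <- vapply(seq_along(planted), function(i) {
    if (config$base_rate == 0) return(NA_real_)
    b_sites <- anc == meta$ancestral[i]
    m_bar <- mean(rate[b_sites, meta$derived[i]]) / config$base_rate
    unname(planted[i]) * (L - meta$length[i] + 1) / (m_bar * L)
  }, numeric(1))
  tibble::tibble(
    context = names(planted),
    multiplier = unname(planted),
    expected_bias = eb
  )
}

#' @export
print.ctxmut_sim <- function(x, ...) {
  cat("<ctxmut_sim> ", x$config$genome_length, " bp, ", x$config$n_focal,
    " focal + ", x$config$n_outgroups, " outgroups, ",
    nrow(x$truth), " planted events\n", sep = "")
  invisible(x)
}

#' Hand-readable micro-alignment fixtures
#'
#' Returns tiny alignments (6 rows, 13-20 columns) that each isolate one
#' behaviour of the mutation caller: a clean biallelic column that must be
#' called, and one fixture per rejection rule (triallelic focal column,
#' gap in a flank, disagreeing outgroups, ancestral allele absent from the
#' population). Expected caller output ships with each fixture.
#'
#' @param name One of `"clean_biallelic"`, `"triallelic"`, `"flank_gap"`,
#'   `"outgroup_disagree"`, `"no_ancestral_match"`.
#' @return A list with `alignment` (list of one `aln_block`), `roster` and
#'   `expected_events` (tibble in [call_mutations()] layout).
#' @export
make_fixture <- function(name) {
  anc <- "ACGACGCGTAGTA" # column 7 is the candidate site (C), flanks ACG / GTA
  mutate_at7 <- function(base) paste0(substr(anc, 1, 6), base, substr(anc, 8, 13))
  roster <- species_roster(paste0("fly", 1:4), c("og1", "og2"), reference = "fly1")
  rows <- c(
    fly1 = anc, fly2 = anc, fly3 = mutate_at7("T"), fly4 = mutate_at7("T"),
    og1 = anc, og2 = anc
  )
  one_event <- tibble::tibble(
    chrom = "chr", pos0 = 6L, ancestral = "C", derived = "T",
    left_flank = "ACG", right_flank = "GTA", derived_count = 2L
  )
  fixtures <- list(
    clean_biallelic = list(rows = rows, expected = one_event),
    triallelic = list(
      rows = `[<-`(rows, "fly4", mutate_at7("A")),
      expected = empty_events()
    ),
    flank_gap = list(
      rows = `[<-`(rows, "og2", paste0(substr(anc, 1, 4), "-", substr(anc, 6, 13))),
      expected = empty_events()
    ),
    outgroup_disagree = list(
      rows = `[<-`(rows, "og2", mutate_at7("G")),
      expected = empty_events()
    ),
    no_ancestral_match = list(
      rows = `[<-`(rows, c("fly1", "fly2"), mutate_at7("A")),
      expected = empty_events()
    )
  )
  if (!name %in% names(fixtures)) {
    abort_ctx("unknown fixture '%s' (available: %s)", name,
      paste(names(fixtures), collapse = ", "))
  }
  fx <- fixtures[[name]]
  list(
    alignment = list(new_block(fx$rows, 0L, "chr", id = 1L)),
    roster = roster,
    expected_events = fx$expected
  )
}
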