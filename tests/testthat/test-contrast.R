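test_that("one event increments exactly its ten window contexts", {
  ev <- tibble::tibble(
    chrom = "chr", pos0 = 0L, ancestral = "C", derived = "T",
    left_flank = "ACG", right_flank = "GTA", derived_count = 1L
  )
  counts <- count_contexts(ev)
  hit <- counts[counts$n > 0, ]
  expect_equal(nrow(hit), 10)
  expect_true(all(hit$n == 1))
  # ancestral 7-mer is ACG.C.GTA -> "ACGCGTA"; all windows over the centre
  expect_setequal(hit$context, c(
    "{C>T|1,C}",
    "{C>T|2,GC}", "{C>T|1,CG}",
    "{C>T|3,CGC}", "{C>T|2,GCG}", "{C>T|1,CGT}",
    "{C>T|4,ACGC}", "{C>T|3,CGCG}", "{C>T|2,GCGT}", "{C>T|1,CGTA}"
  ))
  expect_true(all(count_contexts(ev[0, ])$n == 0))
})

test_that("context counting agrees with the brute-force oracle and is monotone", {
  set.seed(42)
  ev <- random_events(300)
  counts <- count_contexts(ev)
  oracle <- oracle_count_contexts(ev)
  merged <- dplyr::left_join(counts, oracle, by = "context", suffix = c("", "_oracle"))
  expect_equal(merged$n, dplyr::coalesce(merged$n_oracle, 0L))
  # monotone over the subcontext relation
  pairs <- subcontext_pairs(enumerate_contexts(2, 4))
  n <- stats::setNames(counts$n, counts$context)
  expect_true(all(n[pairs$context] <= n[pairs$sub_context]))
})

test_that("contrast arithmetic follows the N/P ratio-of-ratios estimator", {
  counts <- make_counts(c("{C>T|1,CG}" = 30, "{C>T|1,C}" = 100))
  freqs <- make_freq_table(c(CG = 0.05, C = 0.25))
  expect_equal(contrast("{C>T|1,CG}", "{C>T|1,C}", counts, freqs),
    (30 / 0.05) / (100 / 0.25)) # 1.5
  # proportional counts give the null value 1
  counts0 <- make_counts(c("{C>T|1,CG}" = 20, "{C>T|1,C}" = 100))
  expect_equal(contrast("{C>T|1,CG}", "{C>T|1,C}", counts0, freqs), 1)
  # zero context count with observed subcontext
  countsz <- make_counts(c("{C>T|1,CG}" = 0, "{C>T|1,C}" = 100))
  expect_equal(contrast("{C>T|1,CG}", "{C>T|1,C}", countsz, freqs), 0)
  # undefined when the subcontext is unobserved
  countsu <- make_counts(c("{C>T|1,CG}" = 5, "{C>T|1,C}" = 0))
  expect_true(is.na(contrast("{C>T|1,CG}", "{C>T|1,C}", countsu, freqs)))
  expect_error(contrast("{C>T|1,CG}", "{A>C|1,A}", counts, freqs), "subcontext")
})

test_that("mutation bias is the length-1 contrast and telescopes along chains", {
  counts <- make_counts(c(
    "{C>T|2,ACGT}" = 4, "{C>T|1,CGT}" = 11, "{C>T|1,CG}" = 30, "{C>T|1,C}" = 100
  ))
  freqs <- make_freq_table(c(ACGT = 0.004, CGT = 0.013, CG = 0.05, C = 0.25))
  expect_equal(mutation_bias("{C>T|1,C}", counts, freqs), 1)
  bias <- mutation_bias("{C>T|2,ACGT}", counts, freqs)
  chain <- contrast("{C>T|2,ACGT}", "{C>T|1,CGT}", counts, freqs) *
    contrast("{C>T|1,CGT}", "{C>T|1,CG}", counts, freqs) *
    contrast("{C>T|1,CG}", "{C>T|1,C}", counts, freqs)
  expect_equal(bias, chain, tolerance = 1e-9)
})

test_that("minimal contrast picks the defined value closest to 1 with deterministic ties", {
  # counts tuned so the subcontrasts of {C>T|2,ACG} are exactly {1.5, 0.7, 1.1}
  freqs <- make_freq_table(c(ACG = 0.02, AC = 0.05, CG = 0.05, C = 0.25))
  R <- 12 / 0.02
  counts <- make_counts(c(
    "{C>T|2,ACG}" = 12,
    "{C>T|2,AC}" = (R / 1.5) * 0.05,
    "{C>T|1,CG}" = (R / 0.7) * 0.05,
    "{C>T|1,C}" = (R / 1.1) * 0.25
  ))
  expect_equal(contrast("{C>T|2,ACG}", "{C>T|2,AC}", counts, freqs), 1.5)
  expect_equal(contrast("{C>T|2,ACG}", "{C>T|1,CG}", counts, freqs), 0.7)
  expect_equal(contrast("{C>T|2,ACG}", "{C>T|1,C}", counts, freqs), 1.1)
  mc <- minimal_contrast("{C>T|2,ACG}", counts, freqs)
  expect_equal(mc$minimal_contrast, 1.1)
  expect_equal(mc$argmin_subcontext, "{C>T|1,C}")

  # exact tie |1.2 - 1| == |0.8 - 1|: shorter word wins
  freqs2 <- make_freq_table(c(CG = 0.05, GT = 0.05, C = 0.25, CGT = 0.01))
  counts2 <- make_counts(c(
    "{C>T|1,CGT}" = 24, "{C>T|1,CG}" = 100, "{C>T|1,C}" = 500 * 1.2 / 0.8
  ))
  v_cg <- contrast("{C>T|1,CGT}", "{C>T|1,CG}", counts2, freqs2)
  v_c <- contrast("{C>T|1,CGT}", "{C>T|1,C}", counts2, freqs2)
  expect_equal(abs(v_cg - 1), abs(v_c - 1), tolerance = 1e-12)
  mc2 <- minimal_contrast("{C>T|1,CGT}", counts2, freqs2)
  expect_equal(mc2$argmin_subcontext, "{C>T|1,C}") # length-1 beats length-2

  # length-2 context: minimal contrast is forced to equal the bias
  freqs3 <- make_freq_table(c(CG = 0.05, C = 0.25))
  counts3 <- make_counts(c("{C>T|1,CG}" = 30, "{C>T|1,C}" = 100))
  mc3 <- minimal_contrast("{C>T|1,CG}", counts3, freqs3)
  expect_equal(mc3$minimal_contrast, mutation_bias("{C>T|1,CG}", counts3, freqs3))

  # all subcontrasts undefined
  counts4 <- make_counts(c("{C>T|1,CG}" = 0, "{C>T|1,C}" = 0))
  expect_true(is.na(minimal_contrast("{C>T|1,CG}", counts4, freqs3)$minimal_contrast))
})

test_that("the full statistics table is consistent with the single-context operations", {
  sim <- quiet_sim(genome_length = 20000, seed = 8, multipliers = c("{C>T|1,CG}" = 5))
  ev <- call_mutations(sim$alignment, sim$roster)
  freqs <- conserved_words(conserved_mask(sim$alignment, sim$roster))
  counts <- count_contexts(ev)
  st <- context_statistics(counts, freqs)
  expect_s3_class(st, "ctxmut_stats")
  expect_equal(nrow(st), 3744)
  set.seed(2)
  for (ctx in sample(st$context[st$n > 0], 15)) {
    row <- st[st$context == ctx, ]
    expect_equal(row$mutation_bias, mutation_bias(ctx, counts, freqs), info = ctx)
    mc <- minimal_contrast(ctx, counts, freqs)
    expect_equal(row$minimal_contrast, mc$minimal_contrast, info = ctx)
    expect_equal(row$argmin_subcontext, mc$argmin_subcontext, info = ctx)
  }
  # chain identity: contrast(A, C) = contrast(A, B) * contrast(B, C)
  four <- st[st$length == 4 & st$flag == "ok" & st$n > 0, ]
  set.seed(3)
  for (ctx in sample(four$context, 10)) {
    subs <- subcontexts(ctx)
    mid <- subs$context[subs$length == 3][1]
    base <- subs$context[subs$length == 1]
    direct <- contrast(ctx, base, counts, freqs)
    if (is.na(direct)) next
    expect_equal(
      direct,
      contrast(ctx, mid, counts, freqs) * contrast(mid, base, counts, freqs),
      tolerance = 1e-9, info = ctx
    )
  }
})

test_that("the spectrum table reproduces fractions and classes", {
  ev <- tibble::tibble(ancestral = c("C", "C", "G", "A"), derived = c("T", "T", "A", "T"))
  sp <- spectrum_table(ev)
  expect_s3_class(sp, "ctxmut_spectrum")
  expect_equal(sum(sp$fraction), 1)
  expect_equal(sp$fraction[sp$substitution == "C>T"], 0.5)
  g <- glance(sp)
  expect_equal(g$transitions + g$transversions, 1)
  expect_equal(g$transitions, 0.75) # C>T, C>T, G>A; A>T is the transversion
  expect_error(spectrum_table(ev[0, ]), "at least one")

  single <- spectrum_table(tibble::tibble(ancestral = "C", derived = "T"))
  expect_equal(single$fraction[single$substitution == "C>T"], 1)
  expect_equal(sum(single$fraction[single$substitution != "C>T"]), 0)
})
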