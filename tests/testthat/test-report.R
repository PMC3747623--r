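sim_stats <- function(L, seed, multipliers = NULL, ...) {
  sim <- quiet_sim(genome_length = L, seed = seed, multipliers = multipliers, ...)
  ev <- call_mutations(sim$alignment, sim$roster)
  freqs <- conserved_words(conserved_mask(sim$alignment, sim$roster))
  list(stats = context_statistics(ev, freqs), sim = sim)
}

test_that("comparing a bundle with itself gives zero differences, and swaps flip signs", {
  a <- sim_stats(15000, 3)$stats
  b <- sim_stats(15000, 4)$stats
  self <- compare_stats(a, a)
  expect_true(all(self$bias_diff[self$defined] == 0))
  expect_true(all(self$mc_diff[self$defined] == 0))
  ab <- dplyr::arrange(compare_stats(a, b), context)
  ba <- dplyr::arrange(compare_stats(b, a), context)
  expect_equal(ab$bias_diff, -ba$bias_diff)
  expect_equal(ab$mc_diff, -ba$mc_diff)
})

test_that("mismatched context universes are rejected with the difference listed", {
  a <- tibble::tibble(context = c("{C>T|1,CG}", "{C>T|1,CA}"),
    mutation_bias = 1, minimal_contrast = 1)
  b <- a[1, ]
  expect_error(compare_stats(a, b), "\\{C>T\\|1,CA\\}")
})

test_that("a hotspot planted in one species tops the bias-difference ranking", {
  a <- sim_stats(60000, 21, multipliers = c("{C>T|1,CG}" = 8), base_rate = 0.01,
    outgroup_divergence = 0, gap_rate = 0, multiallelic_rate = 0)
  b <- sim_stats(60000, 22, base_rate = 0.01,
    outgroup_divergence = 0, gap_rate = 0, multiallelic_rate = 0)
  cmp <- compare_stats(tidy(a$stats), tidy(b$stats))
  counts_a <- stats::setNames(a$stats$n, a$stats$context)
  counts_b <- stats::setNames(b$stats$n, b$stats$context)
  solid <- cmp[cmp$defined &
    pmin(counts_a[cmp$context], counts_b[cmp$context]) >= 10, ]
  expect_equal(solid$context[1], "{C>T|1,CG}")
})

test_that("scatter data pairs complementary contexts and drops undefined ones", {
  res <- sim_stats(40000, 33,
    multipliers = c("{C>T|1,CG}" = 6, "{G>A|2,CG}" = 6),
    outgroup_divergence = 0, gap_rate = 0, multiallelic_rate = 0)
  sc <- scatter_data(res$stats)
  expect_lte(nrow(sc), 3744)
  expect_false(any(is.na(sc$mutation_bias)))
  expect_false(any(is.na(sc$minimal_contrast)))
  # each pair id appears at most twice and joins a context with its complement
  expect_true(all(table(sc$pair_id) <= 2))
  one <- sc[sc$context == "{C>T|1,CG}", ]
  other <- sc[sc$context == "{G>A|2,CG}", ]
  expect_equal(one$pair_id, other$pair_id)
  # strand-symmetric planting: the paired biases nearly coincide
  expect_lt(abs(log(one$mutation_bias / other$mutation_bias)), 0.5)
})

test_that("packaged reference tables load with their documented shapes", {
  sp <- reference_table("spectrum")
  expect_equal(nrow(sp), 24)
  expect_setequal(unique(sp$species), c("melanogaster", "sapiens"))
  comp <- reference_table("composition")
  expect_equal(nrow(comp), 4)
  repr <- reference_table("representation")
  expect_equal(nrow(repr), 17)
  hc <- reference_table("human_contexts")
  expect_true(all(grepl("^\\{", hc$context)))
  # the published context strings parse with the package's own grammar
  expect_silent(parse_context(hc$context))
})

test_that("pipeline tables survive a TSV round trip", {
  res <- sim_stats(8000, 44)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ctxmut_tsv(tidy(res$stats), path)
  back <- read_ctxmut_tsv(path)
  expect_equal(nrow(back), 3744)
  expect_equal(back$mutation_bias, res$stats$mutation_bias, tolerance = 1e-8)
  # round-tripped tables feed straight back into a comparison
  expect_silent(cmp <- compare_stats(back, tidy(res$stats)))
  expect_lt(max(abs(cmp$bias_diff[cmp$defined])), 1e-9)
})

test_that("tidiers and autoplot produce the documented shapes", {
  res <- sim_stats(8000, 55)
  td <- tidy(res$stats)
  expect_s3_class(td, "tbl_df")
  expect_null(attr(td, "contrasts"))
  g <- glance(res$stats)
  expect_equal(g$n_contexts, 3744)
  p <- autoplot(res$stats, min_count = 5)
  expect_s3_class(p, "ggplot")
  ev <- call_mutations(res$sim$alignment, res$sim$roster)
  sp <- spectrum_table(ev)
  expect_s3_class(autoplot(sp), "ggplot")
  expect_equal(glance(sp)$n_events, nrow(ev))
})
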