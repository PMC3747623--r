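---
title: "Measuring context-dependent mutagenesis with contextmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring context-dependent mutagenesis with contextmut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contextmut)
library(dplyr)
```

## The model

The unit of analysis is the *mutation context* `{mut | pos, W}`: a directed
substitution `mut` sitting at position `pos` of a 1–4 bp word `W`, written
canonically as, e.g., `{C>T|1,CG}` — a C>T mutation at the first position of
the word CG. A context `{mut | pos', W'}` is a *subcontext* of
`{mut | pos, W}` when `W'` is a contiguous subword of `W` containing the
mutated position (remapped to `pos'`): every mutation matching the context
also matches the subcontext. Discontiguous subwords (CNG, CNNG, ...) are not
part of the relation.

For a context and one of its subcontexts, the **contrast** is the ratio of
their conditional mutation probabilities. The absolute probabilities are not
identifiable without an external mutation-rate calibration, but their ratio
is estimated from observable quantities:

$$\mathrm{Contrast} = \frac{N_{\{mut|pos,W\}}/P_W}{N_{\{mut|pos',W'\}}/P_{W'}}$$

where `N` are observed mutation-event counts and `P_W` is the frequency of
`W` among all words of its length. `P_W / P_W'` is the probability that an
occurrence of `W'` extends to `W`, which is exactly the expected count ratio
when the context adds nothing to the rate — so a contrast above 1 means the
longer context elevates the rate relative to the subcontext.

Two summaries are computed per context:

* **mutation bias** — the contrast against the unique length-1 subcontext
  (the bare mutated base): the total excess or deficiency of the mutation in
  the context;
* **minimal contrast** — the subcontext contrast whose value is closest
  to 1: the excess that *no* subcontext explains. A context can have a large
  bias purely by containing a hot subcontext; only a large minimal contrast
  indicates that the full word itself matters.

Because the estimator is a ratio of `N/P` terms, contrasts telescope exactly
along nested subcontext chains: the bias equals the product of contrasts
along any chain from the context down to its single-base subcontext. The
test suite asserts this identity to 1e-9.

## Mutation calling

Events are extracted from a population alignment (N focal genomes, two or
more outgroups) one column at a time. A column yields exactly one event iff:

1. all outgroups carry the same base `b ∈ {A,C,G,T}` — the ancestral state
   (parsimony with agreeing outgroups; no probabilistic reconstruction);
2. at least one focal genome carries `b` and at least one carries something
   else;
3. the focal genomes show exactly two distinct symbols, both bases — any
   gap or ambiguity code disqualifies the column;
4. each of the three alignment columns on both sides is monomorphic across
   *all* rows (focal and outgroups), single base, no gaps. Those six bases
   are the event's ancestral flanks.

Condition 4's "no substitutions or gaps" is read in its strictest consistent
form — monomorphic over focal *and* outgroup rows — because the flanks
define the ancestral context and must be unambiguous; `flank_scope =
"focal"` relaxes it. Columns within three columns of a block edge are never
callable. Each variable column contributes one event regardless of the
derived-allele count (the event, not per-genome observations, is the unit);
the count is recorded. By default every focal genome must be present in a
block for its columns to be callable (`min_focal_present`), the conservative
choice where the data model leaves presence unstated.

Word frequencies for the `P_W` denominators come, by default, from
**conserved regions**: columns where the outgroups agree, no row carries a
gap or unread symbol, and the ancestral base matches at least one focal
variant (so clean biallelic columns are included, scored by their ancestral
base). Words are counted in overlapping windows within maximal runs of
contiguous conserved columns and never across a break. Counting is
plus-strand only; complementary contexts are computed and reported
separately throughout (strand-symmetric pooling would hide polarization
artefacts, and paired complementary points are themselves a useful
diagnostic — `scatter_data()` assigns each context and its reverse
complement a shared pair id).

For the composition of "complete alignments", every ACGT symbol of every
roster row is counted; for conserved regions, the ancestral base per
conserved column. The per-base percent difference is
`(f_all − f_conserved)/f_all × 100`, rounded to one decimal for display.

## Word representation

`representation_score()` measures how far a word's frequency departs from
its compositional expectation: `C = (Obs − Exp)/Exp × 100%`. `Exp` is the
maximal-order Markov estimate built from all subword frequencies of lengths
`k−1` and `k−2`:

$$\mathrm{Exp}(W) = \frac{P(\mathrm{prefix}_{k-1})\,P(\mathrm{suffix}_{k-1})}{P(\mathrm{middle}_{k-2})}$$

with the middle frequency of the empty word set to 1, so the length-2
expectation is the independence product of the single-base frequencies.
Other subword-based estimators exist; this one is isolated behind
`expected_frequency()` so an alternative can be swapped in. The score is
frequency-based, hence invariant under duplicating the input.

## The simulator and what it does (not) emulate

`simulate_population()` is a single-generation star model: one ancestral
sequence drawn i.i.d. from a base composition; per site and substitution an
event probability `base_rate × multiplier(context)`, where the longest
planted context matching the ancestral neighbourhood wins; each event
assigned to a uniformly drawn derived-allele count in `1..N−1`. Outgroups
equal the ancestor apart from private divergence. Defaults mirror a fly-like
resequencing panel: 37 haplotypes, 2 outgroups, AT-rich composition
(A 0.2979, C 0.2022, G 0.2021, T 0.2978), `base_rate` 0.005 events per site
per substitution type (enough at 10^4^–10^5^ bp for hundreds to ~1500
events, the regime where per-context counts are informative but desk-scale),
outgroup private divergence 0.02 per site, gap noise 0.002, multiallelic
noise 5e-4.

Three placement rules keep the planted truth exactly recoverable, and they
are the levers behind the recovery guarantees:

* planted events keep ≥4 columns of spacing and ≥3 columns from the ends,
  so every event retains clean monomorphic flanks (two events 3 bp apart
  would destroy each other's condition-4 windows);
* noise (outgroup divergence, gaps, third alleles) lands ≥4 columns from
  every planted event;
* gaps are never injected into the first focal row, which carries the
  reference coordinates (the simulated alignment has no true indels).

Under these rules the caller's recall and precision on the planted truth are
exactly 1, with or without noise — asserted in the tests.

The model deliberately omits genealogy (allele counts are exchangeable, not
coalescent-distributed), recombination, selection, indel evolution and
shared outgroup branches. The estimators consume only per-column allele
patterns, so none of this affects their validity checks; it does mean that
passing tests certify the *estimators and filters*, not robustness to
demographic structure, alignment error or reference bias in real data.

### What "recovering a planted multiplier" means

The multiplier is a *per-site rate ratio*: context sites mutate at
`m × base_rate`, background sites at `base_rate`. The mutation bias is a
different quantity: its denominator counts mutations at **all** sites of the
ancestral base, hotspot sites included. The generator's true bias for a
planted context on word `W` over base `b` is therefore

$$\mathrm{bias} = \frac{m\,f_b}{f_b + (m-1)\,f_W}$$

(up to an `(L−k+1)/L` edge factor), which approaches `m` only when the
context word is rare relative to its base. For an 8× CpG C>T hotspot under
the fly-like composition, `f_{CG}/f_C ≈ 0.20` and the true bias is ≈3.3 —
indeed no composition with that word share can push the bias past
`f_C/f_{CG} ≈ 5`. `simulate_population()` reports this closed form as
`expected_bias` (computed exactly from the realized rate matrix, including
overlaps between planted contexts), and the recovery tests check the
estimate against it within three binomial standard errors. For the ×3 CCA
context the dilution is small (`f_{CCA}/f_A ≈ 0.04`), so the estimate also
lands within sampling error of the raw multiplier.

## Numerical and degenerate-input policy

* No pseudocounts: a zero subcontext count or zero word frequency makes the
  contrast *undefined* (`NA`, flagged), which is distinct from an observed
  contrast of 0 (`N_ctx = 0` with an observed subcontext). Undefined values
  are excluded from the minimal-contrast search and from plots.
* A context word with zero frequency but a positive mutation count is a
  data inconsistency and raises an error rather than propagating `Inf`.
* Ties in the minimal-contrast search (equal `|value − 1|`) break
  deterministically: shorter subcontext word, then lexicographic word, then
  smaller position. Context enumeration order is fixed (length, word,
  position, derived base), so all outputs are stable across runs.
* Positions are 1-based inside words, matching the context notation;
  genome coordinates are 0-based half-open and converted only at I/O
  boundaries. Minus-strand reference rows in MAF input are flipped to the
  reference plus strand at read time.
* An empty conserved mask yields `NA` conserved fractions in the
  composition summary; an empty event set yields all-zero context counts,
  and the spectrum (a table of fractions) requires at least one event.

## Calibration and detection rules used by the checks

The null-calibration suite simulates 10^5^ bp at context-independent rates
and requires (i) the mean mutation bias per word length to sit in
[0.9, 1.1] — the mean, not a count-conditioned median, because selecting
contexts on large observed `N` selects upward fluctuations by construction —
and (ii) an exact-binomial two-sided test of each context's count against
its single-base expectation (`q = P_W T_k / (P_b T_1)`) to flag at most 1%
of contexts at `p < 10^{-3}` (nominal 0.1%, with slack for the positive
correlation between nested contexts). The representation null check uses the
delta-method standard error `SE(C) ≈ 100·sqrt((1−Exp)/(n·Exp))`, which is
conservative for the Markov estimator since the expectation tracks the
observation.

Problem sizes in the tests — 10^4^–10^5^ bp, 37 haplotypes — are the scale
at which a per-context binomial signal-to-noise of a few hundred total
events is reached in seconds; growing the genome shrinks recovery error as
`1/sqrt(L)` (asserted at two lengths).

## Known limitations

* Two agreeing outgroups give parsimony polarization; parallel mutation on
  both outgroup branches mis-polarizes rare sites in real data. The
  simulator's private-divergence model cannot produce this (divergence is
  placed away from event windows), so the pipeline's robustness to it is
  untested by design.
* Word lengths stop at 4; discontiguous contexts are out of scope.
* Published per-context statistics for a comparison species are consumed as
  a reference table, never recomputed; the packaged tables carry only
  printed values (spectrum fractions, composition, representation scores,
  and the qualitative list of human-hypermutable contexts).
* Contrasts are point estimates; no confidence intervals or multiple-testing
  machinery is attached to the per-context tables.
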