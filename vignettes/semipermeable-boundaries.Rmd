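---
title: "Quantifying gene flow across semi-permeable species boundaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene flow across semi-permeable species boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semiperm)
```

## The problem

When incipient species come back into contact, their boundary is rarely
all-or-nothing: loci near barrier genes resist introgression while the
rest of the genome flows. `semiperm` implements a classical multilocus
workflow for measuring this from phased haplotype alignments of
populations sampled both **in sympatry** (co-occurring with another study
species in a river basin) and **in allopatry** (the species' own reference
basins): per-population polymorphism, between-population divergence and
clustering, a diagnostic-allele introgression classifier, a trend test of
introgression against species divergence, and sympatric-versus-allopatric
polymorphism contrasts. A structured-coalescent simulator with
locus-specific permeability provides datasets with known truth against
which the whole pipeline is validated.

## Statistics and conventions

**Site inclusion.** Every site statistic uses *complete deletion*: a
column containing `-` or `N` in any in-scope sequence is dropped, and the
per-site denominator `L_eff` is the count of surviving columns. The scope
is statistic-specific: within-population statistics delete over the
population's sequences, between-population statistics over the pooled
pair. The two scopes can therefore use different column sets; each
computation records its own `L_eff`.

**Polymorphism.** For a population of `n` gene copies:
`S` = number of analyzed columns with ≥ 2 bases; `Hd = n/(n−1)(1 − Σ p_k²)`
over exact-sequence alleles (indels and Ns participate in allele identity;
this is deliberately conservative and reproducible, whereas masking Ns
for identity would make allele counts depend on coverage);
`K` = mean pairwise mismatch count; `π = K/L_eff`;
`θ_W = S/(a_{n−1} L_eff)`.

**Combining loci.** A combined row sums `S` and `K` across loci, weights
`π` and `θ_W` by per-locus `L_eff` (equivalent to recomputation on a
virtual concatenation of each locus's analyzed columns), and averages `Hd`
unweighted across loci. How the classical tables combined `Hd` across loci
is not derivable from the outputs themselves, so a second mode
(`hd_mode = "concat"`: haplotype diversity of per-sample concatenated
multilocus haplotypes) is available; the unweighted mean is the default
because it is defined even with partially missing samples.

**Divergence.** `D_xy` is the mean between-population per-site distance on
the pooled pair's analyzed columns, `D_a = D_xy − (π_X + π_Y)/2` with both
`π` terms computed on those same columns (this guarantees `D_a ≤ D_xy`
cell-wise), and Hudson's `F_ST = 1 − H_w/H_b` with `H_w` the mean
within-pair `π` and `H_b = D_xy`. `F_ST` is undefined (NA) when
`H_b = 0` and is reported unclamped when negative — downstream consumers
decide. Combined-loci cells weight `D_xy` and `H_w` by per-locus `L_eff`
and recompute `F_ST` from the weighted terms (ratio of averages).

**Neighbor joining.** The Saitou–Nei Q-criterion agglomeration is
implemented directly because determinism is part of the contract: labels
are sorted lexicographically before agglomeration and Q ties are broken by
the lowest (row, column) pair, with merged nodes appended last. Negative
branch lengths are kept and flagged rather than zeroed. Bootstrap support
resamples alignment columns with replacement *independently within each
locus* (preserving locus structure), recomputes the matrix and tree, and
reports the percentage of retained replicates containing each internal
leaf bipartition; replicates with undefined cells (e.g. `F_ST` 0/0) are
dropped and counted, and more than 50% dropped is an error. Whether the
classical workflow resampled jointly across concatenated loci or per locus
is not documented; per-locus is this package's choice.

## The diagnostic-allele rule

For a species pair (A, B) sympatric in a basin, an allele observed in A's
sympatric population is called *introgressed from B* when

1. it has **zero** copies in **every** allopatric population of A, and
2. it has **≥ 1** copy in **any** population of B,

and symmetrically for B. Clause 1 is what excludes shared ancestral
polymorphism: an old allele surviving in A should also survive in A's
allopatric reference. Both directions are classified and pooled into one
per-pair proportion (direction is recorded per call). Note an allele
recently exchanged between the sympatric populations can legitimately
generate calls in both directions when it is absent from both species'
allopatric samples; the proportion counts all such copies.

When a species has **no** allopatric population and is **monomorphic** at
a locus, introgression-with-complete-replacement cannot be distinguished
from retained ancestral polymorphism, so the locus is auto-excluded for
that species' pairs (manual exclusions are also honored and logged).
Excluded loci contribute to neither numerator nor denominator.

**The proportion's denominator.** The classical description ("proportion
of introgressed alleles") does not fix the unit. The default counts gene
*copies* — introgressed copies over all copies sampled in both species'
sympatric populations across included loci — because copy-weighting
reflects introgression load and is stable when allele richness differs
between species; a distinct-allele mode (`mode = "alleles"`) is provided.

**The trend test.** Per-pair proportions are correlated with an externally
supplied, introgression-independent divergence axis (classically mtDNA
uncorrected p-distance from the literature; never recomputed from the
analyzed loci). With `n ≤ 10` pairs the one-sided exact permutation P
under the negative-association alternative enumerates all `n!` rank
permutations: `p = #{ρ_perm ≤ ρ_obs}/n!`. One-sided was inferred because
four perfectly anti-concordant pairs give `1/24 = 0.041\overline{6}`,
matching the classically printed 0.0416 (two-sided would give 0.083).
Ties use mid-ranks, still with full enumeration. `r²` is the squared
Pearson correlation of the raw (divergence, proportion) values — a
regression-through-origin reading was rejected as less standard.

## Sympatry contrasts

The unit of analysis is the population; the value is its combined-loci
statistic. Each of the five measures (S, Hd, K, π, θ_W) gets a
Mann–Whitney U with mid-ranks, tie-corrected σ and **no** continuity
correction (matching the DnaSP-era convention so z ranges are
comparable), two-sided normal P, and the five P values are BH-corrected
as one family. z is positive when sympatric populations rank higher. A
species filter restricts the contrast (classically run within one genus);
which populations the original analysis included is not fully enumerable
from the outputs, so membership is configuration, not code.

## The simulator: what it emulates, and what a green test establishes

Backward-in-time structured coalescent, time in units of `2N₀`
generations, deme sizes relative to `N₀`, `M = 4N₀m`. Demes of one
species merge into the species' first-listed deme at
`within_species_merge_time`; species demes merge up the species tree at
the split times. During a secondary-contact window `[0, start_time]` each
lineage in either connected deme switches demes at rate `M·s/2`, with `s`
the per-locus permeability scalar — a phenomenological stand-in for
selection against introgression at barrier loci (selection itself is not
simulated). Mutations are infinite-sites: `Poisson(θ/2 · branch length)`
per branch, each at a fresh uniformly drawn column (collisions redrawn;
more mutations than columns is an error advising a longer locus),
ancestral state `A`, derived base uniform on `{C, G, T}`. Haploid (mtDNA)
loci use the 0.25 relative-size convention and bare-sample-ID haplotypes.
No recombination within loci; loci independent given the demography.
Indels are **not** simulated — indel handling of the statistics is covered
by hand-written fixtures instead.

The divergence table emulates the external mtDNA axis with a dedicated
zero-migration reference locus, so the axis is independent of the
introgression being measured, as in the classical design.

**Chosen world parameters** (where the analysis design pins none): contact
spans `[0, 0.75]` coalescent units — a long-standing but recent secondary
contact, consistent with Plio-Pleistocene river-capture timescales for
large-`N_e` freshwater fish; same-species demes merge at 1.0; the
four-pair validation panel uses split times 2/6/12/20, spanning
reference-locus p-distances of roughly 1.5%–10%, matching the divergence
span of real multi-species contact systems and wide enough that the
divergence axis essentially never inverts adjacent ranks. An earlier draft
used splits 2/4/6/8; that world failed to realize the stated scenario —
the single-locus divergence estimate inverted adjacent pair ranks in ~40%
of replicates — and was revised once, as recorded in the project notes.

**What a green trend test establishes — and does not.** At the stated
validation scale (10 diploids per deme, 4 nuclear loci of 1000 bp at
θ = 5, M·s = 2/1/0.3/0.05), the per-replicate probability that the four
proportions are strictly ordered is only ≈ 0.5–0.6: with ~160 gene copies
per pair, adjacent migration ratios of 2× are within sampling noise, and
the least permeable pair often yields zero detected copies while its
neighbor sometimes does too. The acceptance criterion (median ρ over 20
replicates equals −1) is therefore intrinsically stochastic-marginal: a
red outcome on an unlucky seed indicates sampling noise at the prescribed
n, not a defective classifier. The deterministic and property-based tests
(exact oracle equivalence, classifier soundness, neutral expectations
`E[K] = θ` and `E[S] = θ·a_{n−1}`, permeability monotonicity) are what
establish correctness; the panel test establishes direction-recovery
power at the stated scale. The generator emulates allele-frequency
structure, sympatric-only sharing and divergence-graded introgression; it
does not emulate indels, recombination, selection, or sequencing error.

Scaling note: the sympatric-power-monotonicity property is run at 40
replicates per migration level in the default suite (a 200-replicate
version behaves identically but is slower than a routine test run should
be); the neutral-expectation checks keep 1,000 replicates.

## Numerical and interface choices

* Column indices are 1-based (R convention) throughout.
* `analyzed_columns` of an empty set, statistics with `n < 2`, and
  `F_ST` with `H_b = 0` raise classed conditions (`semiperm_*_error`)
  rather than returning sentinels; the CLI maps condition classes to exit
  codes 64 (usage), 65 (data), 70 (numeric/simulation).
* Degenerate Mann–Whitney input (all values tied) returns z = 0, p = 1
  with a flag instead of dividing by zero.
* NJ output is unrooted; newick serialization roots arbitrarily at the
  last join.
* Simulation configs serialize as JSON (no TOML parser in the supported
  dependency set); `seed` is mandatory and identical (config, seed) gives
  byte-identical FASTA.
* Missing second copies for a diploid are tolerated with a warning (real
  phased deposits have dropouts); more than two copies per sample and
  locus is a ploidy error.

## Known limitations

* The diagnostic-allele rule detects only *exact* haplotype sharing; a
  migrant haplotype that has since mutated is invisible, so proportions
  underestimate true migrant ancestry (by a roughly divergence-independent
  factor at these timescales).
* The exact trend test enumerates up to `10!` permutations; larger pair
  sets are refused rather than silently approximated.
* Combined-loci `Hd` has no uniquely correct definition; both provided
  modes are documented above.
* The simulator's migrant truth flags mark lineages that crossed demes
  during a contact window, not mutation-visible migrants; truth-based
  power analyses should account for the detection gap.
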