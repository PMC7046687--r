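---
title: "Methods: consensus SNP filtering, diagnostic markers, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus SNP filtering, diagnostic markers, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salmonsnp)
```

## Scope and data model

`salmonsnp` builds a quality-filtered SNP database from three
independent variant-caller outputs over a fixed cohort of Atlantic
salmon: 80 North American (NA) fish from three aquaculture strains
(16 GNB, 53 SJR, 11 PR, each split into year-classes), 31 wild
European fish, and 4 European doubled-haploid (DH) control lines. The
pipeline consumes caller VCFs (with per-sample GT and AD fields), a
BED repeat mask, and a sample metadata table; it does not touch reads
or run the callers themselves.

Internally every caller's output is a `CallSet`: a site table keyed by
the exact `(chrom, pos, ref, alt)` tuple plus genotype-code
(0/1/2/NA) and allele-depth matrices aligned to the roster. Cross-caller
site identity is exact key equality. No left-alignment or allele
normalization pass is applied: only single-base bi-allelic SNPs survive
to the intersection, and those have a canonical VCF representation, so
an exact match is the minimal faithful rule. VCF positions are 1-based
and BED intervals 0-based half-open; all internal coordinates are
1-based, with conversion confined to the BED reader.

## The filtering cascade

Seven stage functions implement the six narrated filtering rules (the
first rule spans three predicates). All are pure site-local set
filters: output ⊆ input, idempotent, order-invariant; the report
preserves the narrated order and satisfies
`records_in − records_removed = records_out` at every stage.

| stage | rule | boundary semantics |
|---|---|---|
| bi-allelic SNP | single-base ref and single single-base alt | multi-allelic and symbolic alleles drop |
| indel proximity | gap to nearest indel reference span ≤ 5 bp | span = `[pos, pos + nchar(ref) − 1]`; gap 0 inside the span; boundary **inclusive** (gap 5 removes) |
| QUAL | keep iff QUAL > 30 | **strict**, per "larger than" |
| repeat mask | position inside the masked intervals | mask merged per chromosome |
| site depth | keep iff summed depth ≤ 3,000 | **inclusive**; "more than 3,000" removes |
| missingness | ≤ 1 missing genotype in the NA roster | counted *after* re-calling; the roster subset is a parameter (the European screen may have used all 115 — the source is not explicit, so the choice is exposed) |
| DH heterozygosity | any heterozygous DH call removes the site | missing DH calls never remove |

Genotype re-calling is a four-way decision on allele depths: alternate
allele present iff ≥ 2 supporting reads, reference present iff ≥ 1;
both ⇒ het, alt only ⇒ hom-alt, ref only ⇒ hom-ref, neither ⇒ missing.
The published rule only states the read-support thresholds; whether it
also re-called homozygotes is ambiguous, and this symmetric four-way
table is the reading implemented (and used by the simulator when it
emits AD fields, so re-calling reproduces emitted genotypes exactly in
the error-free limit).

The depth rule is interpreted as the *site-level total* across all
samples as reported by the caller (DP-style): 3,000 ≈ 26 reads per
sample over 115 fish at 18.5× coverage, consistent with an
"excess total depth" duplication screen rather than a per-sample cap.

The consensus takes genotypes from a designated reference caller
(default: first label alphabetically, i.e. freebayes); cross-caller
genotype discordance on the shared set is counted and reported but not
reconciled, since no merge rule is documented for the original panels.

## Weir–Cockerham Fst and the diagnostic panel

Per-site Fst between the NA and European groups uses the
Weir & Cockerham (1984) two-population moment estimator with the
observed-heterozygosity correction (the per-site formulation popular
through vcftools): components *a* (among populations), *b* (among
individuals within populations), *c* (within individuals), and
Fst = a/(a+b+c), undefined when the denominator is zero or a group has
no data. Missing genotypes are simply excluded; no imputation.

Two numerical choices matter:

* **n̄ = 1 limit.** With one sample per group the 1984 formulas contain
  0/0 products. Whenever a bracket is exactly zero its (possibly
  infinite) multiplier is annihilated, which is the analytic limit; a
  fixed difference then yields Fst = 1 exactly for *any* group sizes
  ≥ 1. This identity is the defining property of the diagnostic panel.
* **Exact membership test.** Panel membership ("Fst = 1") is decided
  combinatorially — every non-missing genotype in one group one
  homozygote class and every non-missing genotype in the other group
  the opposite class — never by floating-point equality on the ratio.

A *candidate* marker is fixed-different in at least one caller's
filtered set; a *high-confidence* marker is present **and**
fixed-different in all three. The panel records both groups' genotype
classes and per-caller Fst values. Group membership (80 NA vs 30 or 31
Europeans — the source counts differ by one) is always explicit input,
never hard-coded.

Per-strain summaries follow the published table semantics: the
per-group SNP count is the number of sites with ≥ 1 non-missing
genotype in the group (the published per-group counts vary slightly,
implying a missingness-dependent denominator); average MAF and average
observed heterozygosity are taken over the group's *polymorphic* sites
only, the stated convention for heterozygosity, applied to MAF for
consistency. MAF histograms default to 0.025-wide right-closed bins on
[0, 0.5].

## Strain phylogeny

The original tree was built with SNPhylo feeding DNAML (maximum
likelihood). Full ML tree search is out of scope here; the documented
preprocessing is kept faithfully — sites on named chromosomes with
MAF > 0.1 (strict), then LD pruning at r² > 0.1 — and the tree method
is substituted with neighbor joining on allele-sharing distances
d(x, y) = mean over co-observed sites of |g_x − g_y|/2, plus a site
bootstrap (resampling matrix columns). The substitution suffices for
the qualitative claim the tree supports (strains separate into
distinct, well-supported clades) and is labelled in the report
(`tree_method`). Distances satisfy symmetry and identity but not
necessarily the triangle inequality; NJ does not require it.

SNPhylo's exact pruning scheme is not documented; the implementation
uses a greedy left-to-right scan in which a site is dropped when its
r² (squared Pearson correlation of genotype codes over
pairwise-complete samples) with any retained site within
`window_size − 1` positions exceeds the threshold. With
`window_step ≤ window_size` this is equivalent, for the retained-pair
guarantee, to the sliding-window formulation; defaults are window 50,
step 5, both configurable. Ties always keep the earlier site;
undefined r² (too few complete pairs, or no variance) never prunes.
Bootstrap supports are counted over canonical bipartition keys of the
reference NJ topology; the seed is mandatory, and NJ join ties resolve
deterministically by input sample order (the `ape::nj`
implementation's fixed scan order).

## The synthetic cohort

The generator's defaults are the study conditions at desk scale:

* **Genome**: 3 chromosomes × 1 Mb, tiled into 2 kb segments assigned
  to masked low-complexity repeat (10%), *hidden* duplication (3%),
  homeologous block (10%), or unique sequence. The BED mask exports
  only the low-complexity intervals. Deep-repeat sites (those whose
  summed depth is forced above 3,000) are placed in the hidden
  duplications precisely because the depth filter exists to catch
  duplications the repeat annotation misses; sites placed inside the
  exported mask would never reach the depth stage.
* **Sites**: ~20,000 planted positions on a 25 bp grid — 15,000 clean
  SNPs, 500 continental fixed differences, 1,000 PSVs, 500 deep-repeat
  sites, 2,000 indels, 500 masked-region SNPs, and 500 SNPs 2–5 bp
  from an indel — so each cascade stage has a truth class that it, and
  only it, must remove. The grid spacing guarantees independent sites
  never interact through the 5 bp proximity rule.
* **Populations**: ancestral allele frequencies Beta(0.8, 0.8)
  (U-shaped, as in an unascertained site-frequency spectrum), truncated
  to [0.02, 0.98]; each continent drifts from the ancestral pool by a
  Balding–Nichols model with F = 0.30, each NA strain from the NA pool
  with F = 0.25 (GNB, PR — few founders) or 0.08 (SJR — broad founder
  base), and each year-class from its strain with F = 0.02. Genotypes
  are Hardy–Weinberg draws within the terminal group; DH samples are a
  doubled haploid draw (never heterozygous); PSV sites are heterozygous
  in every sample including the DH lines — the duplication-collapse
  signature expressed at genotype level rather than by simulating
  mismapped reads, which is sufficient to exercise every downstream
  filter at a tiny fraction of the cost. PSV depth inflation is
  available (`psv_depth_factor`) but defaults off: at 115 samples ×
  18.5× even modest inflation pushes summed depth past 3,000 and the
  depth stage would claim the PSVs before the DH screen can
  demonstrate its effect.
* **Callers**: per-site Bernoulli sensitivity (freebayes 0.90, GATK
  0.93, mpileup 0.97 — ordered as the original per-caller yields),
  false positives at 1% of true sites, genotype error 0.2%,
  missingness 0.5%, 3% of records drawing QUAL below 30, per-sample
  negative-binomial depth with mean 18.5 (dispersion 8; deep-repeat
  sites mean 60 with a deterministic rescue so summed depth always
  exceeds 3,000), and AD fields always consistent with the emitted
  genotype under the re-calling rule. The `noiseless()` helper zeroes
  every noise source, giving call sets identical to truth.
* **Linkage**: none by default (sites are exchangeable), which is what
  the analytic spectrum checks assume; an optional block-copy mode
  (`ld_copy_prob`) copies adjacent genotype columns with 5% per-sample
  switching to create prunable LD for exercising the pruning stage.

What the simulator deliberately does **not** model: read-level error
and mapping, caller error *correlation* (caller mistakes are
independent Bernoulli draws, so the three-caller consensus is, if
anything, more effective on synthetic data than on real data where
callers share alignment artifacts), recombination and realistic LD
decay, and the true PSV spectrum of the salmon genome, which cannot be
estimated from published summaries and is stipulated instead. Passing
recovery tests therefore demonstrates the *logic* of every filter and
the end-to-end bookkeeping, not field performance on real
resequencing data.

## Problem sizes and determinism

The test suite and examples run at deliberate desk scales: full-size
recovery checks at the default 20,000 sites × 115 samples × 3 callers
(a few seconds to simulate, well under a minute to filter), oracle
equivalence on 50 randomized 2,000-site call sets, Fst cross-checks on
1,000 random sites against an independent transcription of the 1984
formulas, and bootstrap trees at 100 replicates (the original analysis
used 1,000; support values stabilize far earlier for the strong
simulated divergence). Every stochastic step takes an explicit seed:
the generator derives its stage seeds from `sim_config(seed)`, the
bootstrap requires one, and a full `run_pipeline()` run is
byte-reproducible — the numeric report deliberately excludes wall-clock
timings, which go to a separate `timings.json`, so that `report.json`
and all artifacts are stable across identical runs.

## Known limitations

* Exact-key consensus will miss concordant sites represented
  differently by callers upstream of the bi-allelic filter (e.g. a SNP
  embedded in a caller's MNP record); the original reconciliation, if
  any, is undocumented.
* Consensus genotypes come from one caller; discordance is reported,
  not resolved.
* The NJ + allele-sharing substitution preserves the qualitative
  strain-separation result, not ML branch-length estimates.
* `strain_summary` percent-polymorphic values depend on the
  missingness-dependent per-group denominator discussed above; with
  the full-cohort missingness cap (≤ 1), the practical difference is
  negligible.
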