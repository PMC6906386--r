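---
title: "dietmir: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dietmir: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(dietmir)
```

This vignette records how each stage of the package is defined, which
choices were genuinely open, and what the synthetic-data tests do and do
not establish. Function reference documentation covers the interfaces; here
the focus is the science and the numerics.

## The analysis problem

Small RNA libraries from the tissues of a phloem-feeding insect are a
mixture: insect-encoded RNAs, RNAs of the obligate endosymbiont, and
ingested material from the host plant, plant-associated bacteria and plant
viruses. The package's stages answer, in order: where does each read come
from; which plant reads are bona fide miRNAs (and are those miRNAs known or
novel); are intact mature miRNAs — rather than degradation fragments —
what the insect tissue contains; and what would those miRNAs regulate if
they acted in either genome.

## Read processing

`process_reads()` applies adapter clipping, quality handling and length
selection, in that order.

* **Adapter dialect.** The leftmost exact match of an adapter *prefix* of
  at least 8 nt, extending to the read's 3' end or covering the whole
  adapter, is clipped (a read-through model). No error tolerance: this is
  the simplest reproducible dialect, and data pre-trimmed elsewhere can
  skip the step (`adapter = NULL`).
* **Quality rule.** The phred-33 threshold (default 28) can be applied two
  ways, because trimming-versus-dropping is underdetermined in most methods
  descriptions: the default trims the 3' end back to the longest prefix
  whose bases all meet the threshold; `quality_mode = "drop"` discards any
  read containing a sub-threshold base. The mode in force is recorded in
  the processing attribute.
* **Length windows.** Two windows are used in practice: 17–35 nt when
  profiling insect tissue reads, 17–25 nt when re-annotating plant miRNA
  precursors from public data. Both are parameters, not constants.

Processing is idempotent: reprocessing an already-processed set is a
no-op (the processing provenance attribute prevents a second adapter pass,
where a biological suffix could occasionally resemble an adapter prefix).

## Source attribution

`match_read()` reports every ungapped placement of a read in a library
with at most `k_max` substitutions, on both strands; `k_max = 1` encodes
the "fewer than two mismatches" rule. An `N` never matches and therefore
costs a mismatch. Matching is delegated to `Biostrings::matchPattern()`
behind this surface; the test suite holds it equal to a position-by-position
Hamming scan on every instance it runs.

`partition_reads()` produces a per-read *membership set* over the five
source categories. Two modes exist because the joint categories (e.g.
insect *and* plant) can only be observed if insect-mapped reads are also
aligned to the plant library:

* `"cascade"` (default): the host-insect and obligate-symbiont libraries
  are interrogated first; only reads unmapped there proceed to the
  plant/bacterial/viral libraries. This mirrors an analysis in which the
  insect genomes are the primary references.
* `"all"`: every read against every library; required for joint-category
  tables.

Within a library, multi-mapping counts membership once: the categories are
set-valued, not placement-valued, so no best-hit resolution is attempted.
`summarize_partitions()` reports mutually exclusive categories (summing to
1 per sample, `unmapped` included) plus `any:` roll-ups, with the sample
standard deviation (n−1); a single-sample group reports `NA`, never a
fabricated 0.

## Precursor annotation

Hairpins are bounded at 300 nt and arms at 20–24 nt. Duplicate calls
across datasets are collapsed by connected components of ≥ 50 % reciprocal
locus overlap on the same strand — the overlap threshold is a package
choice (configurable, logged in the group attribute), since "duplicate"
is rarely given a numeric definition; the retained member is the one with
the most mature-arm reads, ties broken to the lexicographically smallest
dataset id with a warning. Mature/star designation is purely by read
support and deliberately records the arm index, not 5p/3p naming.

The known/novel tree is implemented with literal boundary semantics:

| evidence | verdict |
|---|---|
| precursor e < 1e-10 | known |
| precursor e ≥ 1e-3 | novel |
| middle tier, coverage ≥ 0.60 | known |
| middle tier, coverage < 0.60, min(short e) < 1e-10 | known |
| middle tier, coverage < 0.60, min(short e) ≥ 1e-10 | novel |

An e-value of exactly 1e-10 is *not* known at either tier, and coverage of
exactly 0.60 *is* known; the suite pins every boundary. The short-search
evidence of the two arms is aggregated by the minimum: strong arm-level
homology on either arm suffices for family membership. Reaching the short
branch with no short-search evidence yields `"unset"` with an explicit
error record rather than a silent guess. Query coverage is consumed as
supplied (the search tool's coverage statistic); the package does not
recompute it. Expert-criteria overrides of individual precursors are
representable as input edits, not inferred.

## Detection and profiling

A miRNA is *detected* iff a read equals it exactly, full length, forward
strand. Substring containment is not an observation of a mature miRNA — a
22-mer inside a 30-mer read is a longer RNA — so containment and
reverse-complement matching exist only behind flags for sensitivity
analysis. Length-offset tolerance (isomiRs) is deliberately out of scope.

For profiling, reads are aligned to precursors exactly (no mismatches or
gaps) and classified against the five-region map with the
one-nucleotide-overlap rule: a read belongs to a region if it lies within
that region extended by exactly 1 nt into each adjacent region; overlap of
more than 1 nt with a second region makes it a fragment. For intervals
short enough that two extended regions could qualify (never the case for
real 17+ nt reads over arm-sized regions), mature/star take precedence and
remaining ties go to the region holding the majority of the interval, then
leftmost. A read occurring at several places (or in several precursors) is
counted once at its most specific placement by default
(mature/star > loop/ends > fragment, ties leftmost); `multi = "all"`
counts every occurrence. Region maps assume regions of at least 2 nt.

## Target consensus

The seed region is taken as miRNA positions 2–8 — the canonical choice
shared by the animal-side prediction tools, configurable to wider
plant-style definitions (e.g. 2–13) — and mapped onto the target by
antiparallel pairing: a site `[s, e)` has seed image `[e-8, e-1)`. A
(miRNA, target) pair reaches consensus when every required tool has a site
whose seed images mutually overlap by at least 1 nt; the consensus
interval is their intersection (widest qualifying combination, ties
leftmost). The five external predictors are never executed; their tables
are ingested and normalised to 0-based half-open coordinates at the
parser boundary. Both distinct-target and distinct-pair tallies can be
read from the outputs, since published target counts are ambiguous between
the two.

## COG enrichment

The sampling unit of the null is the 3' UTR, then expanded to isoforms —
a literal reading of resampling procedures phrased as "UTRs were sampled
... then expanded", and the reason a replicate can contain more proteins
than draws. Each replicate draws `n_draws` UTRs uniformly with
replacement, expands, and tallies COG letters; multi-letter assignments
count in every letter on both the observed and null sides so the two are
commensurable. The study-scale replicate count is 1e6; the desk-scale
default is 1e5, and the calibration tests below quantify the Monte Carlo
error at that size.

The two-tailed p-value doubles the smaller inclusive tail and caps at 1.
When the observed count lies beyond every replicate the result is reported
as the bound `< 1/R` rather than 0 — an empirical p of zero is never
claimed. A deviation-from-mean two-tailed construction was considered and
rejected as the default because tail-doubling is well-defined for the
skewed counts that small categories produce; the choice matters only in
the far tails. Significance thresholds per category are the alpha/2 and
1−alpha/2 inverse-ECDF (type-1) quantiles of the null's per-replicate
percentages, converted to the percent-enrichment scale — type-1 quantiles
are used so the thresholds are exactly reproducible by sorting. No
multiple-testing correction enters the significance flags (per-category
p-values are the convention in this analysis); a Bonferroni column is
emitted for the reader.

Degenerate inputs are defined, not errors: a universe of one UTR gives
constant replicates; an observed target set of zero annotated proteins
reports empty; a reference percentage of zero with a positive observation
flags undefined-positive enrichment.

## The synthetic data generator

The generator exists so that every stage has a ground truth:

* genomes are uniform-composition random sequences, rejection-sampled so
  that no two libraries share an exact 17-mer (counting both strands),
  which makes zero-noise provenance unambiguous — reads of 17 nt or more
  cannot match two libraries exactly;
* precursors are built arms-out (5' end + arm + loop + arm + 3' end) with
  the second arm the reverse complement of the first up to a chosen number
  of bulge-free substitutions, and the matching dot-bracket string;
* reads are substrings at planted proportions (the per-origin totals are
  the exact multinomial draw), with substitution-only mutation — no
  indels, because gapped alignments never survive the downstream filters,
  and substitutions keep the brute-force oracles exact; reads are emitted
  forward-strand with a configurable reverse-complement fraction
  (default 0) so strand handling is exercised deliberately;
* target tables plant three pair kinds — consensus (all tools, jittered
  but overlapping seeds), partial (a strict tool subset) and discordant
  (all tools, disjoint seeds) — so the consensus filter has both signal
  and traps;
* proteomes give each UTR 1–3 isoforms and uniform COG letters.

What passing these tests shows: the implementations compute their stated
rules exactly, at the boundaries, and the Monte Carlo machinery is
calibrated. What they do not show: performance on real sequence
composition (repeats, homopolymers, shared ancestry between libraries),
real miRNA family structure, or real phloem sRNA abundance profiles — the
generator makes no attempt to mimic any particular genome.

## Problem sizes and reproducibility

The default test and acceptance sizes are chosen as the smallest at which
the stochastic checks are statistically meaningful: 1000 zero-noise reads
over five 10-kb libraries for attribution recovery; 500 reads against a
50-kb library for the matcher-versus-scan identity; 5000 planted reads for
recovering a 91.4 / 1.8 / 6.8 mature+star / loop / fragment split within
three multinomial standard errors; 1e5 replicates for p-value calibration
against the exact binomial; and 2000 null-drawn experiments (counts of
~Binomial(2000, 0.2), where discreteness of the doubled empirical p is
negligible) for the 0.05 ± 0.01 type-I check. Every stochastic function
takes an explicit seed and is bit-reproducible; the pipeline writes an MD5
manifest and identical seeds yield identical manifests.

## Known limitations

* The internal matcher is exhaustive and simple (no index); it is meant
  for libraries up to a few hundred kb. Genome-scale attribution should
  ingest external ungapped alignments via `parse_alignments()` — gapped
  records are flagged and excluded from category membership to preserve
  the ungapped contract.
* Detection has no mismatch or isomiR tolerance by design.
* The pipeline's command surface is R (`run_pipeline()` plus the stage
  functions); there is no shell CLI, since the intended users work in R
  and the acceptance script covers batch use.
* Probabilistic read assignment, taxonomic LCA logic, quality
  recalibration, paired-end data and de novo precursor discovery are out
  of scope.
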