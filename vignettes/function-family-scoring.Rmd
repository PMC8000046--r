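---
title: "Function;Family observation scoring: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Function;Family observation scoring: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cazyrank)
```

## The model

`cazyrank` quantifies a genome's biomass-degrading enzyme repertoire from
per-protein CAZyme annotations. The unit of analysis is the integrated
**observation key**: the pair of a predicted EC function and the CAZy
family it originates from, serialized `"EC;FAMILY"` (e.g. `3.2.1.4;GH5`).
Two assumptions drive this choice. First, the same catalytic activity
carried by different protein families represents genuinely different
enzymes — different folds, modularity, and biophysical behaviour — so the
key keeps them apart. Second, family membership alone is not function:
records without an EC prediction contribute nothing, and glycosyl
transferases (biosynthetic, not degradative) and LPMO families (no
reliable function prediction from sequence) are excluded outright.

A protein annotated with two EC predictions yields two observation
instances; duplicate identical annotation rows collapse to one. Partial
EC assignments are kept, with the placeholder `*` as fourth field (`-` is
normalized to `*`), so `1.11.1.*;AA2` is a valid, countable key.
Subfamily and CUPP-group suffixes (`GH5_7`, `GH7:2.1`) are collapsed to
the parent family before key construction: the worked unit in the
literature of this method is the family-level key, and subfamily
granularity would fragment counts across annotator dialects. The collapse
is a declared design decision of this package, configurable only by
pre-editing the input.

Each key resolves through a substrate-association map to a weighted
subset of the four targets cellulose, xylan, pectin and lignin. A key
mapped to two substrates counts one half for each; we generalize to 1/k
for k substrates because that is the unique extension preserving the
conservation property the half-rule implies — every mapped instance
contributes total weight exactly 1, so per-substrate scores sum to the
total. Resolution is most-specific-wins: exact EC + exact family, then
exact EC + wildcard family, then wildcard EC + exact family, then the
catch-all. Lignin flows through the identical machinery as the
polysaccharides; it is simply a fourth column.

Per genome and substrate, two scores are accumulated:

* **R\_s** (redundant): every observation instance counted —
  *degradation capacity*, boosted by gene-copy redundancy;
* **U\_s** (unique): every distinct key counted once — *function
  specificity diversity*.

Half-count weights apply to **both** modes. The alternative (integer
unique counts) breaks conservation in unique mode and makes U > R
possible for a substrate; applying one weighting rule uniformly keeps the
invariant U\_s ≤ R\_s, with equality exactly when no key repeats.

The **Redundancy Multiplication Score** is RMS = R/U. Whenever U > 0,
RMS ≥ 1 (instances of each key are at least as many as the key itself).
Reported ratios are rounded half-up to one decimal (so 108/22 prints
4.9); flags are assigned from the *unrounded* ratio — `high` (`*`) above
8, `low` (`¤`) below 3. U = 0 with R > 0 is reported `NA`, never 0 or
infinity: a sentinel avoids injecting a fake ordering into RMS tables.

## Ranking semantics

Rankings are competition style ("1224"): descending score, ties share the
minimum rank and are flagged, and species name is a secondary sort key so
output order is deterministic *without* pretending tied genomes are
ordered. Both the tie-aware rank and the 1..n ordinal position are
emitted, because downstream summaries need each: genus variation
(best/worst/median/spread of ranks per genus, median of an even count =
mean of the central pair) uses ranks, while rank-window phylum
distributions count ordinal positions — windows over competition ranks
could overlap or miss rows at tie boundaries. Default windows are
1–500, 501–1000, 1001–end, trimmed to the cohort size; a window
list must be disjoint and inside the ranking.

## Assembly selection

When one species has several assemblies, the representative is the one
maximizing sequencing coverage × contig N50. N50 here is the largest
length L such that contigs ≥ L cover at least half the assembly — the
common convention, checked in the tests against an exhaustive oracle.
Exact product ties break to higher coverage, then lexicographically
smaller accession; both steps are invented for determinism, since any
choice among product-tied assemblies is defensible. Missing coverage
becomes 0 with a warning — one incomplete metadata record should
deprioritize that assembly, not kill a cohort run.

## The substrate map that ships with the package

`default_substrate_map()` (~45 entries) covers canonical cellulases
(EC 3.2.1.4, 3.2.1.91, 3.2.1.176, 3.2.1.21), xylan-active enzymes
(3.2.1.8, 3.2.1.37, 3.1.1.72, ...), pectin-active enzymes (3.2.1.15,
4.2.2.2, 3.1.1.11, PL families) and ligninolytic activities (1.10.3.2,
1.11.1.13/14/16, AA2), plus two genuinely dual entries (cellobiose
dehydrogenase, feruloyl esterase) exercising the half-count path. It is
an **illustrative** curation: adequate for demonstration, testing and
method development, but not a comprehensive substrate assignment of the
CAZyme universe. Hotspot identities computed on real genomes with this
map reflect the map as much as the genomes; production analyses should
pass a curated map.

## The synthetic generator

`genome_spec()` fixes, per genome: distinct keys per substrate `u`
(ground-truth unique scores), mean copies per key `m ≥ 1`, and a
`dual_fraction` of keys shared between cellulose and xylan. Copy numbers
are `Poisson(m − 1) + 1`: the simplest count model with controllable mean
whose support starts at 1 — a key present in a genome has at least one
gene. Synthetic ECs live in the fictitious leading fields 8–9, so they
can never collide with real map entries. Dual keys pair cellulose with
xylan (the canonical cross-specific pair among plant cell wall glycoside
hydrolases); their count is rounded down to an even integer so the two
half-weights always sum to whole keys and scored U recovers `u` exactly,
which the tests assert seed by seed. Dual keys draw their copy number
from the cellulose multiplier; the generator's distributional invariants
are stated (and tested) at `dual_fraction = 0`, where the choice is moot.

What the generator emulates: controlled repertoire sizes, controlled
redundancy, known rank order, known representative assemblies. What it
does **not** emulate: annotator noise (wrong families, spurious ECs),
correlated key content between related genomes, incomplete assemblies,
and any realistic key-frequency distribution across a cohort. Passing the
recovery tests therefore demonstrates the *scoring machinery* is correct,
not that real annotations are clean.

Validation sizes were chosen to exercise asymptotics while keeping the
default suite fast: exact-recovery and ordering checks use repertoires of
tens to hundreds of keys over 20 seeds; multiplier recovery uses
u = 200 per substrate with m ∈ {1, 2, 4, 8} (mean scored RMS within 5% of
m across seeds); the law-of-large-numbers check uses a single
2000-key genome.

## Numerical choices and degenerate inputs

* Scores are plain doubles; half-weights are exactly representable, and
  profile TSVs are written with 17 significant digits so a write/read
  round trip is bit-exact.
* Reports print scores at one decimal with trailing `.0` dropped,
  matching how such tables are conventionally typeset; full precision is
  retained in the JSON summary.
* Rounding is half-up (away from zero), not banker's rounding.
* An empty annotation table produces an all-zero report with a warning,
  not an error; an empty instance list scores to a zero profile.
* Mixed genome ids in `score_genome()`, metadata-less genomes in
  `rank_genomes()`, overlapping rank windows, unknown substrate tokens
  and ambiguous map matches are all fatal with named diagnostics —
  silent coercion in any of these would corrupt rankings invisibly.

## Known limitations

* Scores count predicted enzymes, not measured activity; secretion,
  expression and kinetics are invisible to the method.
* Capacity scores inherit assembly artifacts: diploid allele contigs
  inflate R (the unique mode partly compensates — this is precisely why
  both modes are reported side by side).
* The key space is only as good as the upstream annotator's EC
  predictions; families without function predictions vanish from the
  analysis entirely.
* Substrate assignment is map-driven and per-key global: the same key
  cannot map to different substrates in different genomes.
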