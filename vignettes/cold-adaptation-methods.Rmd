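---
title: "Methods: screening, detection and cold-adaptation signatures in marine giant viruses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, detection and cold-adaptation signatures in marine giant viruses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryosig)
```

## Scope and model of the data

`cryosig` implements the downstream, desk-scale part of a comparative survey
of giant viruses (phyla *Nucleocytoviricota* and *Mirusviricota*) recovered
as metagenome-assembled genomes (MAGs) from cold (Antarctic, Arctic,
Patagonian fjord) and temperate marine waters. The heavy upstream steps —
sequencing, assembly, binning, gene prediction, HMM searches, read mapping,
orthogroup inference, KO annotation — are deliberately out of scope: the
package consumes their tabular outputs (hit tables, per-base depth tables,
orthogroup and KO membership tables) and implements everything that happens
after them:

1. **Screening** (`screen_genomes()`): which candidate bins are giant
   viruses, under which genetic code, and how do they collapse into
   species-level phylotypes.
2. **Detection and biogeography** (`detection_matrix()`,
   `temperature_profile()`, `endemicity_summary()`,
   `temp_detection_correlation()`): where is each genome present, across
   which temperatures, and how endemic is each source region.
3. **Composition** (`compare_cold_vs_temperate()`): do proteins from cold
   ecosystems differ from temperate ones in amino-acid frequencies and
   physicochemical properties.
4. **Gene content** (`classify_kos()`): which KEGG orthologs are exclusive
   to, or overrepresented in, cold-environment genomes.

A synthetic-data module generates all inputs with known planted structure,
so the full pipeline runs and is validated without any download.

## Screening rules

A candidate bin is called *Nucleocytoviricota* when **more than one
distinct** marker of the seven-gene GVOG set (SFII, RNAPL, PolB, TFIIB,
TopoII, A32, VLTF3) hits with E-value at or below `1e-10`. Distinct markers
are required — two hits to PolB alone do not qualify — because multi-copy
hits to a single marker carry no extra phylogenetic signal. A bin is called
*Mirusviricota* on a **single** passing hit to either the five
morphogenesis markers (HK97-fold MCP, Triplex1/2, Maturation, Portal) or
the four informational markers (RNAPL, RNAPS, PolB, TFIIS). The E-value
cutoff is applied to the full-sequence E-value and is inclusive at the
boundary. Where both rules fire, the NCLDV call takes precedence.

The genetic code of each bin (1, 4, 6 or 11) is the one maximising coding
density — the fraction of base pairs inside the union of predicted coding
intervals, overlaps counted once. Ties, which arise only on degenerate
inputs, break to the lowest code number so the choice is deterministic.

Contamination is gauged by counting hits against 56 cellular single-copy
markers. Clean viral bins show a low copy number; since no universal
threshold exists, the flag threshold is configurable with a default of
"more than 5 total hits".

The phylogeny-based confirmation step of a full analysis (discarding bins
that do not cluster with reference giant viruses in a marker tree) cannot
be reproduced without tree inference, which is out of scope; it is replaced
by explicit `keep`/`drop` lists so that a curator's decisions can be
injected.

Dereplication uses the standard species-rank thresholds — 95% average
nucleotide identity over 85% aligned fraction, both inclusive — on a
user-supplied pairwise table. Clusters are single-linkage connected
components of the thresholded graph; since ANI clustering at species level
is transitive in practice, single linkage is the least surprising choice,
and the representative is the longest genome (ties by id) because longer
MAGs are generally more complete.

## Presence calling and biogeography

A genome is **present** in a sample when its per-base read depth is at
least 2 along at least 70% of its length; otherwise it is absent. The
breadth boundary is inclusive at exactly 70%. The phrase "average depth of
2X along 70% of the length" admits a second reading — 70% of the genome
covered at all, with mean depth over the covered part at least 2 — which is
available as `is_present(method = "mean_covered")`; the per-position
reading is the default because it is stricter and free of the pathologies
of averaging (a single deep spike cannot create a presence call).

To avoid false negatives, only genomes assembled from the pico size
fraction enter the detection analysis directly; genomes from co-assemblies
qualify only when **more than** 70% (strict) of their metagenomic signal
lies in the pico-like fraction (`eligibility_filter()`).

Temperature profiles classify each genome by its detections against three
boundaries (defaults 2, 10 and 18 °C): restricted below the low bound,
detected only below the middle bound, detected above the high bound, or
never detected. The boundaries are arguments, so e.g. a 6 °C class can be
formed, but the defaults are the three canonical ones. A genome's
*endemicity* is binary: it is "unique" when every sample it is detected in
comes from its own source region. Genomes detected nowhere are excluded
from endemicity denominators by default (configurable), since their range
is unobserved rather than narrow.

The temperature–detection relationship is summarised by the Spearman rank
correlation between sample temperature and per-sample detection count, with
a two-sided permutation p-value obtained by shuffling temperatures across
samples. With up to 7 samples all permutations are enumerated, making the
p-value exact; beyond that a seeded Monte Carlo estimate with the add-one
estimator is used. Constant counts or temperatures make the coefficient
undefined; the package reports rho = 0, p = 1 in that degenerate case
rather than erroring, so screening loops need no special-casing.

## Composition comparison

The comparison unit is the protein, restricted to **orthogroups containing
at least one protein from each of the four ecosystems**. This restriction
matters: without it, differences in lineage content between cold and
temperate catalogs would masquerade as compositional shifts. An
orthogroup-mean mode (`unit = "orthogroup"`) averages each metric within
(orthogroup, group) first, for readers who prefer the family as the unit of
observation; the per-protein mode is the default.

Twenty-five metrics are computed per protein: the 20 residue frequencies
and five physicochemical scalars — GRAVY (mean Kyte–Doolittle hydropathy),
Ikai's aliphatic index (`X_Ala + 2.9 X_Val + 3.9 (X_Ile + X_Leu)` in mole
percent), and the contents of acidic ({D,E}), charged ({D,E,K,R,H}) and
polar-uncharged ({S,T,N,Q,C,Y}) residues. Ambiguity codes (X, B, Z),
selenocysteine and stops are excluded from every numerator and denominator,
the standard behaviour of protein property calculators. Histidine is
counted as charged; both this and the polar set are configurable because no
single citation fixes them.

Each cold ecosystem is compared against the temperate pool per metric with
a two-sided Mann–Whitney U test (average ranks for ties; exact enumeration
when the combined sample is at most 12 without ties, else normal
approximation with tie and continuity correction), preceded by a
Shapiro–Wilk normality check per group, reported alongside. Because 25
metrics are tested per ecosystem, Benjamini–Hochberg adjusted p-values are
reported within each ecosystem in addition to the raw ones; a rank test
was chosen over a t-test precisely because per-protein frequency
distributions are skewed for rare residues.

## KO prevalence ratios

Gene-content enrichment works on genome-level KO presence. Genomes are
pooled into cold (the three cold ecosystems) versus temperate, following
the pooled design of the emulated comparison; a per-ecosystem mode is
available through `cold_envs`. For each KO the prevalence (carrier fraction)
is computed per pool and summarised as
`ratio = prev_cold / (prev_cold + prev_temp)`:

* `ratio = 1.0` → **cold-exclusive** (absent from the temperate pool);
* `ratio >= 0.75` (i.e. at least 3× more prevalent, boundary inclusive)
  → **cold-overrepresented**;
* KOs carried by fewer than 2 genomes of a pool in which they occur are
  **filtered** as sporadic. A KO absent from a pool is not filtered on
  that pool's side: absence is informative, not sporadic.

The boundary at exactly 0.75 is counted as overrepresented, matching the
"at least 3 times more prevalent" selection rule; internally the ratio is
computed from integer carrier counts
(`n_cold·N_temp / (n_cold·N_temp + n_temp·N_cold)`) so boundary cases like
6/20 versus 3/30 evaluate to exactly 0.75 rather than to a floating-point
neighbour. The ratio is scale-free: multiplying both pool sizes by any
constant leaves it unchanged. Selected KOs are summarised per functional
category with `category_breakdown()`; KOs missing from the category map are
reported as "unmapped" rather than dropped.

## The synthetic-data module

The generators emulate the statistical structure each stage assumes, at a
desk scale chosen once:

* **Pools**: 8 Antarctic + 6 Arctic + 6 Patagonian = 20 cold genomes versus
  30 temperate — a scaled-down version of a cold-biased survey catalog, and
  a pool geometry in which an exact 3:1 planted prevalence (6/20 vs 3/30)
  is representable in whole genomes.
* **Proteomes**: 10 proteins per genome, lengths ~ Normal(300, 60) floored
  at 50 residues; residues drawn i.i.d. from Swiss-Prot background
  frequencies, with cold genomes drawn from background + a shift vector
  (default +0.01 threonine / −0.01 leucine, a canonical psychrophilic
  signature). Residue-wise i.i.d. sampling carries no positional structure
  — sufficient because every downstream metric is composition-only, and a
  stated non-goal to go beyond. Orthogroups are assigned cyclically within
  each genome so each of the 10 groups spans all four ecosystems.
* **KO tables**: planted cold-exclusive KOs (4 cold carriers, 0 temperate),
  planted exactly-3× KOs (6/20 vs 3/30), and background KOs at equal
  prevalence. Carrier counts are fixed ("exact-count construction") so the
  planted classes are recovered deterministically; a Bernoulli mode exists
  for probabilistic behaviour.
* **Depth profiles**: exactly `round(breadth × length)` positions at depth
  ≥ 2 (seeded shuffle), the rest alternating 0/1, so the target breadth is
  recovered exactly and the 69/70/71% presence boundary is deterministic.
* **Samples**: temperatures spanning −1.4 to 30 °C, cold sources drawing
  from the cold end, with the extremes pinned so the collection always
  spans the range.

What the generators do **not** emulate — real phylogenetic correlation
between proteins, shared evolutionary history within orthogroups, coverage
unevenness from GC or mappability, compositional differences between viral
families — bounds what passing tests demonstrate: they validate the
statistics and decision rules, not robustness to every property of real
metagenomes.

## Numerical choices and degenerate inputs

* Inclusive boundaries: E-value 1e-10, breadth 0.70, ANI 95 / AF 85, ratio
  0.75 all pass their thresholds; the pico-signal filter for co-assemblies
  is strict (> 0.70) as befits its "more than 70%" definition.
* Genetic-code ties break to the lowest code number; dereplication
  representative ties break lexicographically.
* The Mann–Whitney exact/approximate switch sits at combined n = 12 with
  continuity correction on; Shapiro–Wilk subsamples (seeded) above its
  n = 5000 domain.
* Empty hit lists classify as "neither"; empty depth vectors, empty
  orthogroup member environments and empty pools error loudly.
* The problem sizes used by the validation suite — 200 proteins per side
  and 100 replicates for shift recovery and null calibration, exhaustive
  permutation at up to 6 samples, enumeration of all label assignments at
  combined n ≤ 8 for the rank test — were chosen as the smallest scales at
  which the planted effects are comfortably detectable and enumeration
  stays instantaneous.

## Known limitations

The pipeline inherits every upstream limitation of its inputs: marker hit
tables decide what can be screened, depth tables what can be detected.
Dereplication consumes an ANI table rather than computing ANI; the
phylogeny-confirmation step is delegated to keep/drop lists; and the KO
E-value filtering is assumed to have happened upstream (tables are taken
as-is). Presence calls are binary by design — abundance estimation is a
non-goal — so downstream statistics treat a barely-present genome and a
dominant one identically.
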