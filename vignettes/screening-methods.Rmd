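---
title: "Screening low-frequency somatic and germline variants from deep read counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening low-frequency somatic and germline variants from deep read counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vafscreen)
library(dplyr)
```

## The problem

Deep amplicon sequencing of blood-cell DNA (depths of 100,000–300,000 reads
per locus) can detect somatic variants present in only a few percent of
cells. At those fractions the signal competes with the sequencing error
background, so "is this individual a carrier?" is a thresholding problem:
where does the background end? `vafscreen` implements the screening design
used to study a recurrent somatic 3'-UTR variant of the MAP4K3 (GLK) kinase
gene in systemic lupus erythematosus (SLE) cohorts, as a reusable pipeline:

1. **Quantification** — the variant read frequency at a locus is simply
   `alt_reads / depth` (`variant_frequency()`).
2. **Control-derived cut-off** — carriers are individuals whose frequency
   exceeds the mean plus three sample standard deviations of the non-case
   group, the clinical-laboratory outlier convention behind Westgard
   quality-control rules (`westgard_cutoff()`). Mean + 3 SD covers ≈99.7% of
   a normal background, so frequencies above it are unlikely to be noise.
3. **Association** — carrier status against case status in a 2×2 table,
   tested with a two-tailed Fisher exact test (`fisher_exact_2x2()`).
4. **Germline variants** — read frequencies near 50% (heterozygous) or 100%
   (homozygous) indicate inherited variants; allele frequencies are computed
   over family-deduplicated unrelated subsets (`dedup_unrelated()`,
   `allele_frequency()`).
5. **Annotation** — the gene sits on the minus strand of chromosome 2, so
   genomic alleles must be complemented and repositioned to name variants in
   cDNA, protein, or 3'-UTR terms (`genomic_to_cdna()`,
   `annotate_codon_change()`), and the 3'-UTR is scanned for AU-rich
   elements (`scan_are()`), the mRNA-destabilising segments in which the
   index variant sits.
6. **Clinical comparison** — laboratory covariates (anti-dsDNA, complement
   C3/C4, blood counts, SLEDAI) compared between carrier groups with
   Student's t-tests (`compare_clinical()`).

No patient-level sequencing data are distributed; a synthetic-cohort
generator (`simulate_cohort()` and friends) reproduces the statistical
structure the inference assumes, so the full pipeline is testable end to
end.

## The cut-off

Given control frequencies \(x_1,\dots,x_n\), the threshold is
\(\bar{x} + 3s\) with \(s\) the sample SD (\(n-1\) denominator — the QC
convention; the choice is invisible at \(n = 163\)). The published screen
computed 1.0% + 3 × 0.58% = 2.74% and applied it as 2.7%; accordingly
`westgard_cutoff()` truncates the applied threshold to one decimal of a
percent by default (`round_cutoff = FALSE` disables this), and reports both
values:

```{r}
tidy(cutoff_from_summary(0.010, 0.0058, n = 163))
```

Carrier calls use strict `>` against the applied cut-off by default, since
that is the screen's dominant phrasing; an inclusive `>=` mode exists
because the boundary semantics are genuinely ambiguous in the source
material. At the depths involved the distinction almost never matters, but
it is surfaced rather than hidden.

## The exact test

`fisher_exact_2x2()` is implemented from first principles: with the margins
fixed, the probability of every admissible table is accumulated in log
space (`lchoose`), and the two-tailed p-value is the sum of probabilities
of all tables no more probable than the observed one — the probability-mass
two-tailed rule used by standard implementations. A relative tolerance of
1e-7 absorbs floating-point ties. The test suite verifies exact agreement
with a literal `choose()`-product enumeration oracle on every 2×2 table
with total at most 40, and with `stats::fisher.test()` on random tables.

```{r}
fisher_exact_2x2(matrix(c(17, 84, 0, 163), 2, byrow = TRUE))
```

## Family de-duplication

Allele frequencies must be computed over unrelated individuals. The rule:
keep all sporadic patients and non-familial controls; from each family keep
exactly one patient and one unaffected member. The kept representative is
the member with the lexicographically smallest ID — the source never states
which member it kept, and the choice cannot change any count, only the
excluded-ID report. The resulting denominator (2 alleles per individual)
depends only on the sporadic and family counts, never on family sizes: the
discovery-cohort configuration (24 sporadic + 62 families) always yields
86 unrelated patients and 172 alleles.

## The gene model

Mapping runs through anchored blocks: cDNA position `cdna_anchor + k`
corresponds to genomic position `genomic_anchor − k` on the minus strand.
The packaged model (`glk_gene_model()`) uses a 2685-nt CDS — implied by the
published pairs c.3320 ↔ 3'-UTR 635 and c.3329 ↔ 3'-UTR 644, since UTR
continuation numbering is `cdna_pos − cds_length` — and four blocks
anchored on published coordinate/label pairs. All published pairs are
mutually collinear (e.g. 39,477,820 − 39,477,124 = 696 = 3320 − 2624), so
one block per coordinate cluster reproduces every printed label; block
extents beyond the anchors, the filler CDS codons and the UTR flanks are
synthetic and documented as such. UTR position 1 anchors to chr2:39,477,758
(= 39,477,124 + 634), confirmed by the round-trip identity test over every
in-model position.

Protein annotation rebuilds the affected codon from the CDS context,
substitutes the alternate base, and translates both codons through the
standard genetic code, yielding `p.Ala410Thr`-style labels (`Ter` for stop
gains, `p.(=)` for synonymous changes). Frameshift labels for out-of-frame
insertions name the codon containing the first position after the insertion
point (`c.1942_1943insA` → `p.Ala648fs`). In-frame indel consequences and
the full HGVS grammar are out of scope; 3'-UTR variants are labelled both
in continuation style (`3'-UTR U635C`) and HGVS starred style (`c.*635T>C`).

## AU-rich element calling

No universal ARE definition exists, so `scan_are()` states its rule
explicitly: every sliding window of `min_length` (default 60 nt) with A+U
fraction ≥ `min_au` (default 0.65) qualifies; overlapping qualifying
windows are merged; each merged segment is trimmed to its outermost A/U
bases and re-checked against both thresholds. Trimming prevents GC flanks
captured by straddling windows from diluting a segment. On the packaged
synthetic UTR this calls a single 62-nt element (positions 603–664,
69.4% AU) containing both screened UTR variant positions.

## The synthetic-cohort generator

The generator's defaults are the study conditions:

| quantity | default | origin |
|---|---|---|
| discovery cohort | 24 sporadic + 62 families (77 familial patients, 157 relatives) + 6 HCs | published composition |
| replication cohort | 80 sporadic patients, 87 HCs | published composition |
| depth | uniform 100,000–300,000 reads | published depth range |
| control background | mean 1.0%, SD 0.58% | published control moments |
| somatic clone fraction | uniform 2.7–5.3%, 17 carriers (cohort 1) / 37 + 14 HC (cohort 2) | published carrier counts and range |
| germline heterozygote | success probability 0.5 | binomial sampling model |
| ages | medians 31 (patients, cohort 1), 43.5 (cohort 2), 40/42 (controls) | published medians; reporting-only |

The background error model is generative: each individual draws a
background rate from a zero-truncated normal, and each cell draws
`alt ~ Binomial(depth, rate)`. Naively truncating Normal(1.0%, 0.58%) at
zero would inflate the realized mean by about 0.05 percentage points —
enough to fail a moment-recovery check at n = 10,000 — so the generator
solves for the underlying normal parameters whose truncated distribution
has exactly the requested mean and SD. The requested moments therefore
describe the background actually simulated, which is what the published
moments describe too. Somatic carriers add a single clone fraction on top
of background (no clonal mixture structure — none is published), and
multi-case families are configurable (two families in the discovery
composition carry two patients each, mirroring the published pedigrees).

Clinical covariates are normal draws per parameter with carrier-group
shifts in the published directions (anti-dsDNA and SLEDAI up; C3, C4,
white cells, lymphocytes, platelets down). No patient-level values are
published, so baselines are typical lupus-clinic values chosen once
(e.g. C3 90 ± 25 mg/dL, WBC 6000 ± 1800/µL) with shifts of 0.8 baseline
SDs where the published comparison is significant and 0.5 SD for SLEDAI
(published as a non-significant trend). What passing tests show is that
the *inference machinery* has the right power and type-I behaviour under
these effect sizes — not that real SLE laboratories look like these
distributions. Likewise the generator does not emulate FASTQ-level
artifacts, strand bias, PCR duplicates, or age-dependent clonal
haematopoiesis; conclusions about those require real data.

All randomness flows from one integer seed in documented order (roster at
`seed`, read counts at `seed + 1`, clinical at `seed + 2`), and identical
configurations give bit-identical tables.

## One worked run

```{r, fig.width = 6, fig.height = 4}
cfg <- sim_config_cohort1(seed = 1)
roster <- simulate_cohort(cfg)
counts <- simulate_read_counts(roster, glk_loci(), cfg)
scr <- screen_locus(counts, roster, "T635C")
glance(scr)
autoplot(scr)
```

The recovered cut-off sits near 2.7% and the association p-value far below
1e-4; across 200 seeded replicates of this configuration the raw cut-off
stays within [2.4%, 3.1%] and the association holds in over 95% of runs
(this is the end-to-end recovery test in the suite).

## Numerical and design notes

- **Degenerate inputs.** Zero-variance controls give cutoff = mean; an
  all-zero contingency table returns p = 1 with a warning; zero pooled
  variance with equal means gives t = 0, p = 1; a frequency at exactly the
  background floor is background (floors are inclusive downward), and the
  applied cut-off is exclusive under strict mode.
- **t-tests.** Pooled-variance Student is the default (it is the test the
  comparisons name); Welch is available behind `welch = TRUE`. One-tailed
  directions must come from the analyst: the defaults follow the published
  effect directions. Missing laboratory values are dropped per parameter,
  so each comparison reports its own n. No multiplicity adjustment is
  applied across the seven parameters, matching the source presentation;
  treat marginal p-values accordingly.
- **Problem sizes in the suite.** Property tests use 10,000–12,000 draws
  for calibration and uniformity checks, 200 replicates for end-to-end
  recovery, and full enumeration of 2×2 tables to total 40 — sizes at which
  the Monte-Carlo error of each check is far below its assertion margin.
- **Known limitations.** Single-clone somatic model; fixture-scale gene
  model (not the full exon structure); no external population allele
  frequencies (database-dependent); SLEDAI consumed as given, never
  rescored.
```
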