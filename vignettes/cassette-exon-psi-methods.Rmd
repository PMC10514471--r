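---
title: "Methods: junction-read PSI, cis-element annotation and donor-site scoring for a muscle-specific cassette exon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-read PSI and cis-element annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cassPSI)
```

## The biological setting

GFPT1, the rate-limiting enzyme of the hexosamine biosynthetic pathway,
carries a 54-nt cassette exon that is spliced in almost exclusively in
striated muscle of mammals, producing the muscle-specific long isoform.
The exon keeps the reading frame (54 nt = 18 codons in human; the mouse
exon is 48 nt = 16 codons), its donor site is weak, and its inclusion is
tuned by position-dependent splicing regulators: SRSF1 enhancer motifs in
the exon, hnRNP H/F G-runs in the exon (silencers) and downstream intron
(enhancer), and a (U)GCAUG Rbfox element in the downstream intron. This
package implements the computational layer of that analysis: PSI
quantification from splice-junction counts, motif annotation with
position-rule effect calls, donor-site strength evaluation, and the
derived metabolic indices used to characterize the knockout — together
with a synthetic-data generator that stands in for the raw sequencing
data, which are not redistributed here.

## PSI from junction reads

For a cassette exon between two constitutive exons, three junction
classes are informative: the two flanking-intron junctions (inclusion
evidence) and the exon-bridging skip junction (exclusion evidence). An
included transcript contributes *two* junction-spanning reads where a
skipped transcript contributes one, so inclusion reads are half-weighted:

$$\mathrm{PSI} \;=\; \frac{0.5\,I}{E + 0.5\,I},$$

with $I$ the pooled flanking-junction reads and $E$ the skip-junction
reads. `classify_junctions()` matches records against the gene model at
**both** intron boundaries exactly; no tolerance window is applied,
because any fuzzy-matching policy would need arbitrary parameters and
risks absorbing unrelated junctions. Junctions on other sequences or with
shifted boundaries are simply ignored.

Conventions and edge cases:

* All internal coordinates are 0-based half-open; STAR's 1-based
  inclusive intron coordinates are converted once, in `read_star_sj()`.
  Under this convention both printed genomic spans used as sanity checks
  (a 72-nt deletion and a 120 + 54 + 100 = 274-nt minigene insert) equal
  `end - start` exactly, which fixed the interpretation of printed
  "start-end" loci.
* PSI is **undefined** (NA), not zero, when $I = E = 0$: absence of
  evidence is not exclusion evidence. Undefined estimates are excluded
  from aggregation and tallied.
* Only unique-mapping reads are counted by default. Whether multi-mapped
  junction reads should contribute is not decidable from first
  principles; unique-only is the conservative choice and
  `count_mode = "all"` exposes the alternative.
* No minimum-read filter is applied by default: low-evidence estimates
  are reported with their read support (`total_reads`) so that displays
  can encode support rather than hide it. `min_reads` suppresses
  low-evidence PSIs when desired.
* Group summaries use the unweighted mean and the sample (n−1) SD across
  datasets, appropriate for the small numbers of datasets per tissue;
  population SD is available as an option.

## The synthetic junction-count generator

The generator defines the study conditions under which the estimator is
validated. Per dataset at true inclusion $\pi$ and depth $\lambda$
(expected informative fragments): $I \sim \mathrm{Poisson}(2\lambda\pi)$,
split $\mathrm{Binomial}(I, 1/2)$ between the two flanking junctions, and
$E \sim \mathrm{Poisson}(\lambda(1-\pi))$. Then
$\mathbb{E}[0.5I] = \lambda\pi$ and $\mathbb{E}[E] = \lambda(1-\pi)$, so
the plug-in estimator is consistent, with $O(1/\lambda)$ ratio bias.
Poisson is the minimal noise model consistent with independent fragment
sampling; a negative-binomial `dispersion` option exists for robustness
checks but is off by default. Decoy junctions are written with every
boundary at least 2 nt away from the model's boundaries, so exact-match
classification has unambiguous ground truth.

The default tissue panel (`fig_profile_muscle()`) encodes the measured
isoform fractions: $\pi = 0.83$ in skeletal muscle, $\pi = 0.35$ in
heart, $\pi = 0$ elsewhere, across four mammalian species, three
datasets per group, $\lambda = 200$. The species/tissue grid is a
reduced-size emulation of the public multi-tissue RNA-seq collections
(11 tissues in the originals); reducing the grid changes nothing about
the estimator, only the breadth of the display. What the generator does
**not** emulate: mappability artifacts, overdispersion between biological
replicates, annotation errors in the gene model, and reads supporting
other isoforms — so passing recovery tests here demonstrates correctness
of the estimator under its stated sampling model, not robustness to every
failure mode of real RNA-seq.

```{r psi-demo}
tr <- simulate_junction_counts(pi = 0.83, lambda = 500, n_datasets = 200,
                               seed = 7)
psis <- mapply(compute_psi, tr$inclusion_up, tr$inclusion_down, tr$exclusion)
round(c(mean = mean(psis), sd = sd(psis)), 4)
```

## Cis-element annotation

Motif scanning works on a `region_sequence()`: one nucleotide string
partitioned into `upstream_intron | exon | downstream_intron`. RNA motifs
from the literature are matched in DNA space after U→T normalization.

* **SRSF1 (SR-protein) sites** are scored with an additive
  position-weight matrix; the bundled matrix is the published ESEfinder
  SF2/ASF score table, under which the two exonic enhancer motifs score
  CACACGG = 5.86 and CACAGGG = 5.25, and the default reporting threshold
  is the ESEfinder convention, 1.956. (Of the two published SRSF1 matrix
  variants, only the standard SF2/ASF matrix reproduces both motif
  scores, which settles the choice of default.) Every window is scored;
  thresholding is applied at reporting time.
* **Rbfox elements**: every GCAUG occurrence is reported, with a note
  when preceded by U/T (the (U)GCAUG element).
* **G-runs**: maximal runs of at least `min_run` guanines (default 3,
  the shortest run treated as an hnRNP H/F element; maximality means a
  run is never a sub-run of a longer one).

Each hit carries a `predicted_effect` from the position rules —
SR proteins enhance from the exon and repress from introns; hnRNP H/F do
the reverse; Rbfox enhances from the downstream intron and represses from
the exon or upstream intron. These are annotations of binding-position
logic, not predictions of measured splicing outcomes. A hit that
straddles a region boundary has no unambiguous position class and is
reported with region `NA` and effect `not_applicable`.

`motif_conservation()` tabulates presence/absence of motif specifications
across species and flags motifs present throughout a designated clade and
absent outside it — the signature of the mammal-restricted regulatory
architecture.

## Donor-site strength

The 5′ splice site is the 9-mer of exonic positions −3..−1 and intronic
+1..+6. The consensus used is (C/A)AG|gt(a/g)ag(t/g); although the
consensus string in the splicing literature continues with a 10th
position, the site itself is defined over −3..+6 and only those positions
are evaluated. `consensus_mismatches()` reports deviating positions: the
weak natural donor GAG|gtggga deviates at −3, +4 and +6; the optimized
donor GAG|gtaagt only at −3.

Two scorers are provided behind one interface:

* `maxent_5ss_score()` implements the maximum-entropy donor model: the
  near-obligate GT at +1/+2 is scored by marginal frequencies against
  background, and the remaining 7 positions by a table of $4^7$
  probabilities. The reference tables are third-party model files,
  located via `options(cassPSI.maxent_dir = ...)`; the expected file is
  `me2x5`, 16384 numeric lines, one per 7-mer in lexicographic A<C<G<T
  order. When the tables are absent the scorer raises an explicit
  "unavailable" error — never a silent fallback — because scores from
  different models are not comparable. With the reference tables the weak
  and optimized donors score 4.3 and 11.08.
* `build_pwm_5ss()` trains a position-wise log2(frequency/0.25) matrix
  from example sites with a pseudocount (default 0.25; a zero pseudocount
  with an unobserved letter is rejected rather than yielding −Inf).

The SD score, a published donor-strength metric that requires a
genome-wide annotated splice-site corpus to compute, is deliberately not
re-implemented; `score_donor_site()` accepts externally computed values
as pass-through columns for side-by-side display.

## Derived metabolic indices

`adenylate_energy_charge()` and `guanylate_energy_charge()` compute
(NTP + 0.5·NDP)/(NTP + NDP + NMP) — in [0, 1], undefined on an empty
pool, scale-invariant, and monotone in the triphosphate.
`metabolite_ratio()` computes plain concentration ratios
(lactate/pyruvate and malate/aspartate are the default NADH/NAD⁺
surrogates); group summaries are mean ± SEM, and inferential statistics
are intentionally out of scope. Metabolite names are matched
case-insensitively, and UDP-HexNAc resolves to UDP-GlcNAc + UDP-GalNAc
when only the components are present. The metabolite generator draws
multiplicative lognormal noise around configured group means (default
sdlog 0.1, a realistic ~10% CV for targeted metabolomics); the knockout
scenario used in the analysis scripts raises lactate/pyruvate by 20% and
malate/aspartate by 50% over wild type.

## Numerical and design notes

* All generators restore the caller's RNG state; determinism is
  byte-level (two runs of the pipeline with one seed produce identical
  tables, with timestamps confined to the run log).
* Pipeline runs are write-once: a non-empty output directory is an
  error, so no run can silently mix artifacts from two configurations.
  Output TSVs carry a provenance comment (package version +
  configuration hash); the hash covers parameters only, not paths, so
  the same analysis in two directories matches bytewise.
* Problem sizes used by the validation suite — 500 datasets per
  inclusion level at depth 500 for estimator recovery, 100 random 1-kb
  sequences per scanner for oracle equivalence, 1000 random junction
  fixtures for classification — were chosen to make Monte-Carlo error
  comfortably smaller than the tolerances asserted (estimator bias
  < 0.02) while keeping the suite desk-scale.
* Known limitations: single cassette triplet per model (no genome-wide
  annotation handling); exact-boundary matching assumes the gene model
  matches the aligner's genome build; motif effect calls encode position
  logic only; the maximum-entropy scorer requires externally obtained
  tables.
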