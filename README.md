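# cassPSI

Junction-read quantification and cis-regulatory annotation of a
muscle-specific cassette exon.

## The problem

GFPT1, the rate-limiting enzyme of the hexosamine biosynthetic pathway,
has a frame-preserving 54-nt cassette exon (18 codons; 48 nt / 16 codons
in mouse) that is included almost exclusively in mammalian striated
muscle, producing the muscle-specific long isoform. Characterizing that
switch computationally requires four pieces, which this package
implements for anyone analysing a cassette exon from splice-junction
evidence:

1. **PSI quantification.** From splice-junction count tables (STAR
   `SJ.out.tab` or 6-column junction BED), junctions are classified
   against a three-exon gene model by exact boundary matching, and
   percent spliced-in is estimated with half-weighted inclusion reads
   (an included exon spans two junctions, a skipped exon one):

   PSI = 0.5·I / (E + 0.5·I)

   where I pools the two flanking-junction read counts and E is the
   skip-junction count. PSI is NA (not 0) when I = E = 0. Estimates
   aggregate per (species, tissue) as mean / sample SD with total read
   support.

2. **Cis-element annotation.** Additive PWM scanning for SR-protein
   exonic splicing enhancers (the published ESEfinder SF2/ASF SRSF1
   matrix is bundled; threshold 1.956), (U)GCAUG Rbfox elements, and
   hnRNP H/F G-runs — each hit annotated with the position-rule effect
   (e.g. exonic SRSF1 sites enhance, exonic G-runs silence,
   downstream-intron Rbfox sites enhance), plus presence/absence
   conservation matrices across species.

3. **5′ splice-site strength.** Consensus-mismatch reporting against
   (C/A)AG|gt(a/g)ag(t/g), a maximum-entropy donor scorer driven by
   externally supplied reference tables, and a frequency-trained PWM
   fallback scorer.

4. **Derived metabolic indices.** Adenylate/guanylate energy charges
   ((NTP + 0.5·NDP)/(NTP + NDP + NMP)) and metabolite ratios
   (lactate/pyruvate, malate/aspartate) with group mean ± SEM.

A seed-deterministic synthetic-data generator produces every input with
known ground truth (Poisson junction counts with binomial junction
split; planted-motif sequences; lognormal metabolite tables), so the
whole pipeline is testable without downloading sequencing data.

## Worked example

Simulate the default multi-species tissue panel (true inclusion 0.83 in
skeletal muscle, 0.35 in heart, 0 elsewhere), quantify and aggregate:

```r
library(cassPSI)
res <- run_psi_pipeline("demo_run", seed = 1, lambda = 200, n_datasets = 3)
subset(res$summary, species == "mouse")
#>  species          tissue n_datasets  mean_psi     sd_psi total_reads
#>    mouse           brain          3 0.0000000 0.00000000         586
#>    mouse           heart          3 0.3490076 0.01784020         809
#>    mouse          kidney          3 0.0000000 0.00000000         590
#>    mouse           liver          3 0.0000000 0.00000000         633
#>    mouse            lung          3 0.0000000 0.00000000         604
#>    mouse skeletal_muscle          3 0.8189629 0.01623546        1105
```

The estimator recovers the muscle-restricted inclusion pattern from
junction counts alone: mean PSI ≈ 0.82 in muscle and ≈ 0.35 in heart
(close to the configured 0.83 / 0.35, within sampling error at this
depth), exactly 0 elsewhere; `total_reads` is the informative read
support used for display weighting. `demo_run/psi.tsv` holds the
per-dataset estimates, `demo_run/psi_summary.tsv` the aggregate, and
rerunning with the same seed reproduces both byte for byte.

Donor-site and motif queries print the field's reference numbers:

```r
consensus_mismatches("GAGGTGGGA")   # weak natural donor GAG|gtggga
#> [1] -3  4  6
srsf1 <- read_pwm(system.file("extdata", "srsf1_sf2asf_pwm.tsv",
                              package = "cassPSI"))
score_pwm_window(srsf1, "CACACGG")  # 5.86
score_pwm_window(srsf1, "CACAGGG")  # 5.25
```

## Analysis workflow

The `analysis/` directory holds the narrative drivers, each a thin
script over the package functions, writing tables under `results/`:

| script | output |
| --- | --- |
| `01_simulate_panel.R` | simulated junction panel (`results/panel/`) |
| `02_quantify_psi.R` | per-dataset PSI + tissue summary |
| `03_scan_motifs.R` | motif hits + species conservation matrix |
| `04_score_donor_sites.R` | donor-site consensus/scorer report |
| `05_metabolic_indices.R` | energy charges and redox-surrogate ratios |

Run them in order with `Rscript analysis/01_simulate_panel.R` etc.

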