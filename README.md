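# chargescape

Proteome-wide protein charge distribution and its impact on translation.

As a protein is synthesized, the nascent chain passes through the ribosome
exit tunnel — a negatively charged channel holding about 30 residues.
Positively charged nascent segments can interact with the tunnel walls and
slow elongation, so the placement of charged stretches along protein
sequences is both a structural and a translational trait. `chargescape` is
an R package for scientists who want to quantify that landscape:

* **Residue ionization model** — per-residue fractional charges from the
  Henderson–Hasselbalch equation at a chosen pH (default 7.4), with a
  back-solved pKa set reproducing the canonical three-decimal charges
  (Lys +0.999, Arg +1.000, His +0.048, Glu −0.999, Asp −1.000,
  Cys −0.085, α-amino +0.996, α-carboxyl −1.000), integer or
  three-decimal rounding, configurable histidine convention (0 or +1) and
  optional termini charges.
* **Charge landscape** — the net charge of every 30-residue window
  (the exit-tunnel length): sign fractions, negative/positive ratio
  curves, per-position terminal charge averages, N/core/C-terminal
  heat-map matrices with per-tile support, and detection of supercharged
  stretches (|net charge| ≥ 14) with 60-aa context for downstream signal
  prediction.
* **Ribosome occupancy** — per-codon profiling counts are coverage-
  filtered (< 50% covered positions eliminated), depth-normalized per
  gene (mean exactly 1), grouped by the net charge of the first 30
  residues (≥+8, +7, +6, +5, 0, −1, −6, ≤−7), and summarised as metagene
  curves and AUC ratios over codons 0–90 against the charge-0 group.
* **Monosome/polysome stratification** — genes classified into
  ORF &lt; 590 nt / monosome / no-enrichment / polysome / top-300-polysome
  categories, with per-category charge histograms, segment means and
  charge-bin composition tables.
* **Synthetic data with ground truth** — generators for proteomes
  (positional K/R bias, planted supercharged stretches, signal-peptide
  prefixes), per-codon counts with a charge-dependent occupancy multiplier
  and its closed-form expected readout, and monosome:polysome scores with
  tunable charge/length coupling. Every pipeline stage is validated
  against planted truth.

For each window of width $W = 30$ starting at residue $i$, the net charge
is

$$ Q_i \;=\; \sum_{j=i}^{i+29} q(a_j), \qquad
   q(\text{base}) = \frac{+1}{1+10^{\mathrm{pH}-pK_a}}, \quad
   q(\text{acid}) = \frac{-1}{1+10^{pK_a-\mathrm{pH}}}, $$

rounded per the active mode. The AUC ratio of a charge group $g$ is the
trapezoidal area of its metagene curve over codons 0–90 divided by that of
the charge-0 reference group.

## Worked example

```r
library(chargescape)

tab <- charge_table()   # pH 7.4, His = 0, integer rounding, termini off
p <- window_scan("MSKRKSTKAKVAKTWLKSDDEDEFADFENSEDEELLAHHHKTA", tab, id = "demo")
p$window_charges
#>  1  2  3  4  5  6  7  8  9 10 11 12 13 14
#>  0 -1 -2 -4 -6 -7 -7 -7 -8 -8 -9 -8 -8 -9
```

Window 1 (residues 1–30) holds 7 basic and 7 acidic residues — net 0;
sliding toward the acidic C-terminal half drives the net charge down to
−9. Histidines count 0 under the default mode.

A full synthetic occupancy experiment: 600 proteins whose first windows
are forced to charges +9, 0 and −6 (200 genes per group), counts drawn
with the default occupancy response (2.0× over codons 0–90 for ≥+8,
0.8× for −6):

```r
g   <- gen_proteome(n_proteins = 600, nterm_charges = c(9, 0, -6), seed = 42)
rb  <- gen_ribo_counts(g$proteome, seed = 43)
occ <- ribosome_occupancy(g$proteome, rb$counts)
occ
#> Ribosome occupancy by N-terminal charge group
#>  group n_genes       auc auc_ratio
#>     -6     195  75.22492 0.8393789
#>   >=+8     199 144.31151 1.6102647
#>      0     197  89.61975 1.0000000
```

The ≥+8 group shows a 1.61-fold AUC over the reference — less than the
planted 2.0× multiplier because per-gene depth normalization absorbs part
of the early-codon surplus; the generator's analytic expectation table
(`rb$expectation`) predicts exactly this attenuated value, and the
estimates land within a percent of it. The −6 group shows the planted
deficit (0.84 vs analytic ≈ 0.84).

End-to-end runs with TSV outputs and a reproducibility manifest:

```r
run_charge_pipeline(list(
  outdir = "run1", seed = 7,
  simulate = list(n_proteins = 500, n_supercharged = 5, ribo = TRUE, mp = TRUE)))
```

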