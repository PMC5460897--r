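---
title: "Proteome charge landscapes and translation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteome charge landscapes and translation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chargescape)
```

## The scientific question

During synthesis the nascent polypeptide threads through the ribosome exit
tunnel, a ~100 Å channel that holds roughly 30 residues and carries a net
negative electrostatic potential. Positively charged nascent segments can
interact with the tunnel walls and slow elongation. `chargescape` provides
the computational side of that story: it quantifies where charged
30-residue segments sit in proteomes, and relates the net charge of the
first 30 residues (the segment filling the tunnel when the ribosome reaches
codon ~90) to ribosome occupancy and to monosome/polysome partitioning.

## The residue ionization model

Each ionizable group is modelled by Henderson–Hasselbalch at a single
solvent pH (default 7.4). A base contributes
$+1/(1+10^{\,\mathrm{pH}-\mathrm{p}K_a})$, an acid
$-1/(1+10^{\,\mathrm{p}K_a-\mathrm{pH}})$; all other residues are exactly 0.
Charges are reported to three decimals; the default analysis mode rounds
them to the nearest integer, which makes every downstream window sum exact
integer arithmetic.

The bundled pKa set (Lys 10.40, Arg 12.00, His 6.10, Glu 4.40, Asp 3.90,
Cys 8.43, α-amino 9.80, α-carboxyl 3.10) is **back-solved**: the values
were chosen so that the three-decimal charges at pH 7.4 equal the canonical
set (+0.999, +1.000, +0.048, −0.999, −1.000, −0.085, +0.996, −1.000)
exactly, rather than copied from one published pKa table. Each entry can be
overridden via `charge_table(pKa = ...)` or a YAML config
(`read_charge_config()`), so any preferred reference scale can be swapped
in. The Cys value in particular should be read as a fitted constant, not a
literature value.

Histidine is treated specially. Its effective pKa in proteins ranges from
roughly 2.4 to 9.2 depending on environment, and in an unfolded peptide it
sits near 6.5, i.e. mostly neutral at physiological pH. The rounded-charge
convention for His is therefore a mode, not a consequence of the pKa:
`his_mode = "zero"` (default, the physiological choice) or `"plus_one"`
(the convention of earlier charge surveys, kept for comparability). The
mode governs only the rounded charge; the fractional charge is always the
Henderson–Hasselbalch value (+0.048 at pH 7.4).

Free-termini charges (+0.996 / −1.000) are off by default — the default
analysis mode deliberately ignores them, since a 30-residue window in the
middle of a chain has no free termini — and can be enabled together with
three-decimal rounding to reproduce the fully fractional variant of the
calculation. The two modes give nearly identical charge distributions,
which is why the simpler integer mode is the default everywhere.

Ambiguity codes (B, Z, X, and the rare letters U, O, J) carry charge 0
with a warning; non-letter symbols are errors. Lowercase input is
uppercased.

## The window scan and landscape statistics

`window_scan()` computes the net charge of every 30-residue window
(window $i$ = residues $i..i+29$, 1-based inclusive; a protein of length
$L$ has $L-29$ windows) by a rolling cumulative sum. The brute-force
per-window sum is kept as the test oracle; the two agree exactly on
thousands of random sequences because integer mode never leaves integer
arithmetic.

Landscape summaries follow directly:

* **Sign fractions** — the proportions of windows with positive, zero and
  negative net charge. "Neutral" means exactly 0 under integer rounding
  and exactly 0.000 in three-decimal mode.
* **Negative/positive ratio curve** — for each magnitude $q$,
  $\#\{\text{windows} = -q\} / \#\{\text{windows} = +q\}$. Magnitudes with
  no positive windows are reported missing (`NA`), never as 0, so a
  one-sided tail cannot masquerade as symmetry.
* **Per-position terminal means** — the average residue charge at each of
  the first/last 30 aligned positions; position 1 is always the initiator
  methionine and hence 0.
* **Heat-map matrices** — mean window charge per window-start offset for
  the N-terminal region (starts 1–100), the core (starts 130–230) and the
  C-terminal region (the last 100 window starts, labelled −129..−30
  relative to the sequence end). Proteins shorter than the full span
  contribute only the tiles they possess; every tile records its support
  and zero-support tiles are `NA`. We chose support-weighted means over
  excluding short proteins because proteome length distributions vary
  widely and exclusion would silently bias organism comparisons. A
  consequence worth noting: for a protein of exactly 129 residues the
  N-terminal and C-terminal tile sets are the same 100 windows — regions
  are coordinate conventions, not disjoint partitions.
* **Supercharged stretches** — maximal runs of consecutive window starts
  whose |net charge| ≥ 14 (sign-specific). Each run is reported once, with
  its first qualifying start, peak charge, and the window plus the next 30
  residues (60 aa of context, truncated at the protein end and flagged),
  ready for export to external localization-signal predictors. Collapsing
  overlapping windows into runs means counts refer to stretches, not to
  qualifying windows, which would otherwise overcount a single charged
  region ~k times for a run of k windows.

`nc_terminal_correlation()` relates the first-window and last-window
charges by Pearson correlation across proteins of length ≥ 60, so the two
windows can never overlap; shorter proteins are excluded with a count.
Zero variance in either margin yields `NA`, reported as undefined rather
than 0.

`correlate_with_trait()` reproduces the normality-gated correlation
procedure used for trait tables: both margins are tested with the
D'Agostino–Pearson omnibus K² test (skewness and kurtosis z-scores,
$K^2 = z_s^2 + z_k^2 \sim \chi^2_2$) at α = 0.05; Pearson is used if both
pass, Spearman otherwise, and the chosen method is always reported. The
omnibus test is implemented in the package (no installed R package
provides it) and is validated in the test suite against reference values
computed with an independent implementation. The gate needs n ≥ 8; below
that the function refuses and tells the user to choose a method
explicitly.

## Ribosome occupancy by N-terminal charge

The pipeline starts from per-codon read counts (gene, 0-based codon,
count); adaptor trimming, rRNA removal and alignment are upstream concerns
of the sequencing workflow, not of this package. Processing is:

1. **Coverage filter** — genes with fewer than 50% of codon positions
   carrying ≥ 1 read are eliminated. The boundary (exactly 50%) is
   retained, because the rule removes strictly sub-threshold genes.
2. **Normalization** — each gene's counts are divided by its mean count,
   so every normalized profile has mean exactly 1 and a flat metagene sits
   at 1. Dividing by the total instead (a `divisor = "total"` switch)
   differs only by the gene-length factor; the mean divisor is the default
   because it gives the interpretable baseline.
3. **Charge groups** — genes are grouped by the rounded net charge of
   their first 30 residues into eight categories: ≥+8 (charges +8..+13),
   +7, +6, +5, 0, −1, −6 and ≤−7 (−7..−15). Charges outside the listed
   ranges are unassigned. An optional mitochondrial group (from GO
   annotation) can be reported alongside; annotation groups may overlap
   the numeric ones.
4. **Metagene** — at each codon 0..150 the unweighted mean of normalized
   values across genes long enough to reach that codon, with per-position
   support. Equal gene weighting (rather than read-weighting) keeps
   deeply sequenced genes from dominating the curve.
5. **AUC ratio** — the trapezoidal area of a group's curve over codons
   0–90 (the span corresponding to the first 30 amino acids) divided by
   the area of the charge-0 reference curve. The reference's own ratio is
   exactly 1. Because every gene is normalized to its own depth, the
   ratio is invariant to global scaling of the raw counts — an identity
   the tests assert exactly.

The codon range 0..90 is treated in the profile's native unit (one entry
per codon); "codon 0" is the start codon position.

## Monosome/polysome stratification

Genes are classified into five categories: `orf_lt_590` (ORF < 590 nt,
regardless of any score — for such short ORFs initiation time exceeds
elongation time, so they are translated largely by monosomes), `monosome`,
`no_enrichment`, `polysome`, and `top300_polysome` (the 300 most
polysome-skewed scores among polysome-classified genes; disjoint from
`polysome`). The primary input mode is a precomputed label table, because
the original experimental category boundaries belong to the upstream
dataset; when only a monosome:polysome log-ratio score is available, the
package falls back to symmetric thresholds (default ±0.5, configurable)
around 0. An ORF of exactly 590 nt goes to the score/label branch.

Per category, the package reports the window-1 charge histogram and sign
fractions, and mean ± SE of the N-terminal (window 1), core and C-terminal
(last window) charges. The core window start defaults to 121 (residues
121–150), with `core_start = 130` available — the two conventions coexist
in the literature and the package records the choice rather than
resolving it.

`charge_bin_group_percentages()` inverts the conditioning: proteins are
binned into 16 N-terminal-charge bins (≤−7, each integer −6..+7, ≥+8) and
each bin is decomposed into category percentages. Rows sum to 100% by
construction, the size-weighted average of rows reproduces the overall
baseline exactly, and empty bins are missing rows rather than fabricated
zeros.

## What the synthetic generator emulates — and what it does not

`gen_proteome()` produces proteomes with: lognormal lengths (default
meanlog = log 400, sdlog = 0.45, floor 60 aa — a realistic eukaryotic
protein-length distribution), a yeast-like baseline composition, an
additive K/R probability boost (default +0.08 split over K and R) at
positions 3–10 emulating the N-terminal positive enrichment, a mild D/E
boost (+0.02) elsewhere emulating the slightly negative core, optional
signal-peptide-like prefixes (basic residue then a hydrophobic stretch),
and optional planted supercharged stretches. Frequencies are renormalized
to sum to 1 at every position, and every protein starts with methionine.

Planted stretches place their charged residues at both edges of the
30-residue block and surround it with four counter-charged flanking
residues. This construction makes the planted window start the unique
first qualifying start: any window shifted by $j$ loses at least
$\min(j,\lfloor q/2 \rfloor)$ units of block charge and gains
counter-charge from the flank, so localization is exact for target
magnitudes up to one unit above the detection threshold (the default
target +15 against threshold 14). Ground truth (offsets, targets, signal
flags) is returned with the sequences.

`gen_ribo_counts()` draws a per-gene depth from a lognormal (default mean
2 reads/codon), applies a multiplicative occupancy factor $m(q)$ over
codons 0–90 as a function of the window-1 charge — default piecewise: 1
for −5 ≤ q ≤ +4, rising linearly to 2 at q ≥ +8, dropping to 0.8 at
q ≤ −6, i.e. a two-fold occupancy gain for strongly basic N-termini —
and then draws negative-binomial counts (size 10; Poisson available for
closed-form checks). The effect is applied to the expected counts before
depth normalization, matching the causal picture in which slowly
translated codons accumulate ribosome footprints.

The generator derives the analytic expectation of the AUC-ratio readout
from its own parameters: a gene of $L$ codons with multiplier $m$ over $e$
effect codons has expected normalized occupancy
$mL/(em + L - e)$ in the effect region (exactly 1 if the whole gene is
affected), and a group's expected AUC ratio is the gene-mean of this
quantity relative to the reference group. Recovery tests therefore
compare the pipeline estimate to a closed form, not to a second
simulation. The expectation uses the ratio of expectations rather than
the expectation of the per-gene ratio; the difference is $O(1/L)$ and far
inside the 10% recovery tolerance at the default problem sizes.

`gen_mp_scores()` couples a Gaussian score to log2 ORF length (default −1
per doubling, centred) and to window-1 charge (default +0.15 per unit),
so positive charge pushes genes toward monosomes and length toward
polysomes. With both couplings zero the score is independent of charge —
the null under which bin percentages must match the baseline within
multinomial sampling error.

What the generator does **not** emulate: real residue correlations along
sequences (domains, low-complexity regions), codon-level determinants of
elongation (codon usage, tRNA supply, mRNA structure), uORFs, and the
composition idiosyncrasies of real organisms. Passing recovery tests
therefore demonstrates that the pipeline measures what it claims on data
whose generating process is known — not that any particular biological
effect size in real data is confirmed.

## Numerical choices and degenerate inputs

* Integer mode never leaves integer arithmetic; fractional mode carries
  three-decimal values, and the rolling sum is re-rounded once per window
  only in integer mode to guard against floating drift.
* Division-by-zero contracts are explicit everywhere: ratio-curve
  magnitudes with no positive windows are `NA`; zero-variance
  correlations are `NA` with a warning; a zero-read gene cannot be
  normalized (and cannot occur after the coverage filter); an empty
  metagene group and a zero-area reference curve are errors.
* Proteins shorter than the window are skipped with a counted warning —
  never a hard error — so ragged real proteomes flow through.
* All generators take an explicit seed, restore the caller's RNG state,
  and are bit-reproducible; the pipeline writes a manifest with the md5
  of every output and of the config that produced it, making whole runs
  regression-testable byte for byte.

## Problem sizes used in validation

The bundled checks run at desk scale, chosen so the full suite completes
in well under a minute while keeping Monte-Carlo error far from the
tolerances: the window-scan oracle uses 1,000 random sequences; positional
bias recovery uses 2,000 proteins (≈3 standard errors of the per-position
mean); occupancy-multiplier recovery uses 200 genes per charge group at
mean depth 2 reads/codon (10% tolerance against the analytic expectation);
the null-coupling test uses 5,000 proteins with a Bonferroni-adjusted
multinomial band. These sizes are the package's validation conditions,
stated here so that users scaling up to real proteomes know what has been
demonstrated.

## Known limitations

* Single global pH and context-free pKa values: no folded-state pKa
  shifts, no isoelectric-point machinery.
* GO annotation matching is exact-ID; no ontology-graph traversal.
* The monosome/polysome score thresholds are conventions, not inferred
  boundaries; with label input the package inherits whatever upstream
  definition produced the labels.
* The metagene treats position in profile units (codons); it does not
  model A-site offsets or nucleotide-resolution effects.
* Heat-map regions overlap for short proteins by construction (see
  above); downstream consumers that need disjoint regions must filter by
  length first.
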