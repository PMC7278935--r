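---
title: "Quantifying very long-chain fatty-acid elongation from yeast GC-MS assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying very long-chain fatty-acid elongation from yeast GC-MS assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlcfa)
library(dplyr)
```

## The biological problem

Very long-chain fatty acids (VLC-FA, chains longer than C24) are built by
Elovl4 elongases, which extend an acyl chain by two carbons per catalytic
cycle. Teleost fish carry two paralogs, Elovl4a and Elovl4b, whose
substrate preferences differ between species and whose products —
VLC-saturates in brain sphingolipids, VLC-polyunsaturates in retinal
phosphatidylcholine — are critical during early neural development. The
standard functional assay expresses a candidate elongase heterologously in
*Saccharomyces cerevisiae* (which has no PUFA elongation activity of its
own), feeds one exogenous PUFA substrate per culture, and reads out the
fatty-acid methyl ester (FAME) profile by GC-MS in selected-ion-monitoring
(SIM) mode. This package implements the computational side of that assay:
the nomenclature and SIM-channel arithmetic, the conversion statistic and
its inversion, the group statistics applied to saturated-FA profiles, the
biosynthesis pathway graph, the diagnostic sequence analyses, qPCR absolute
quantification, and a seeded simulator that stands in for the unpublished
raw chromatograms.

## Nomenclature and SIM channels

Fatty acids are written in the field's shorthand `C:Dn-x` (chain carbons,
double bonds, omega series), e.g. `22:6n-3` for DHA. The parser enforces
the chemistry (`carbons >= 2*double_bonds + x` for unsaturated chains) and
round-trips with the formatter. Elongation never creates odd chains, but
the parser accepts them because odd-chain species occur in real GC-MS
tables.

Saturated FAME are monitored on their molecular ion. For a chain of `c`
carbons and `d` double bonds the methyl ester is C~c+1~H~2(c+1)−2d~O~2~,
and the reported channel is the monoisotopic mass (C 12.000, H 1.00783,
O 15.9949) rounded half-up to one decimal:

```{r}
fame_molecular_ion_mz(c("24:0", "26:0", "28:0", "30:0", "32:0", "34:0"))
```

Nominal (integer) masses do not reproduce the C30–C34 channels, which is
why the monoisotopic convention with half-up rounding is used throughout;
`base::round()`'s half-to-even rule is deliberately avoided. Polyunsaturated
FAME are monitored instead on the three diagnostic polyene fragments m/z
79.1, 108.1 and 150.1; the package treats the per-species "area" as a
single response and takes no position on whether instruments sum or select
among the three fragments, since either choice cancels in the statistic.
Monounsaturates (the yeast background 16:1n-7 and 18:1n-9) are grouped
with the molecular-ion channel.

## The conversion statistic and the cascade model

Let `A_sub` be the substrate peak area and `a_k` the area of the k-th
elongation product (substrate + 2k carbons), and define the tail sums
`S_k = a_k + a_{k+1} + ...` with `S_0 = S_1 + A_sub`. The per-product
conversion reported in the assay is, in this package's default
**stepwise** mode,

    c_k = 100 * S_k / S_{k-1}

i.e. the fraction of material that reached product k−1 and was elongated
at least once more. The published description of the calculation ("area of
first product and longer chain products / (that + substrate area)") admits
a second, literal reading with the supplied substrate in every
denominator,

    c_k = 100 * S_k / (S_k + A_sub)

kept as mode `cumulative_literal`. The two readings coincide at k = 1. The
choice of default is not cosmetic: the literal reading is provably
non-increasing in k (x/(x+const) is increasing and tails shrink), yet the
published DHA columns rise from a few percent at the first step to 100 at
the second — a shape only the stepwise reading can produce. The package
therefore defaults to stepwise and retains the literal mode explicitly;
the monotonicity contrast is asserted in the test suite.

Under a steady-state cascade in which a fraction `e_k` of the material at
chain length k−1 is elongated again, the amounts are
`A_k = a0 * e_1...e_k * (1 − e_{k+1})`, the tail sums telescope to
`S_k = a0 * e_1...e_k`, and the stepwise statistic returns exactly `e_k`.
This algebraic identity is what `estimate_step_efficiencies()` inverts
(trivially in stepwise mode; through the tail-sum recursion
`x_k = c_k/(100−c_k)`, `e_k = x_k/x_{k−1}` in cumulative mode), and what
`conversions_to_areas()` uses to reconstruct relative areas from a printed
conversion column. Because the raw peak areas behind the published tables
were never released, those tables cannot be recomputed from scratch; what
*can* be checked — and is, for all 28 printed substrate × construct
columns bundled under `extdata` — is self-consistency: reconstructing
areas from a column and re-applying the statistic reproduces the column
exactly at one decimal, including its `n.d.` pattern.

Products are reported `n.d.` (not detected) when the product and every
longer product fall below the detection limit; a detected product with a
genuinely zero conversion prints 0.0. The detection limit defaults to 0
and is caller-supplied for simulations; raising it can only convert
detected entries to `n.d.`, never the reverse. Conversions are rounded
half-up to one decimal by default, matching the published tables; passing
`digits = NULL` disables rounding where full precision matters (the
identity above holds to machine precision and is tested at 1e-9).

## Saturated-FA profiles and group comparison

The VLC-SFA assay has no exogenous substrate; instead the triplicate
(`n = 3`) profiles of transformed versus control yeast are compared after
expressing each saturated species from 24:0 to 34:0 as a percentage of
their summed areas (`sfa_percent_profile()`, which always totals 100
within rounding). `compare_groups()` applies the battery used in the
study: Levene's homogeneity test — centered at the group means, matching
SPSS, rather than `car`'s Brown–Forsythe median default — one-way ANOVA at
alpha 0.05, and all-pairs Tukey HSD summarized as a compact letter
display. The letter display is computed by insert-and-absorb over the
Tukey significance matrix; `multcomp::cld` serves as an independent
cross-check in the tests, never as the implementation. Letters are
assigned to groups ordered by ascending mean by default ("a" = lowest),
with `letter_order = "descending"` available because published tables are
not consistent in this convention. A Levene rejection is reported but does
not block the ANOVA, and no multiple-testing correction is applied across
fatty acids — both choices mirror the study design.

## The pathway graph

`build_reference_pathway()` encodes the LC-/VLC-PUFA biosynthesis network
as a typed edge list (elongation, desaturation, beta-oxidation), from the
C18 precursors through Δ6/Δ5 desaturation and elongation to EPA/ARA, and
onward through the Elovl4 elongation families to a C36 ceiling. Two
species profiles matter here: gilthead seabream synthesizes DHA by the
Sprecher route (22:5n-3 → 24:5n-3 → Δ6 → 24:6n-3 → one round of partial
β-oxidation → 22:6n-3), Senegalese sole by direct Δ4 desaturation of
22:5n-3; both lack *elovl2*. β-oxidation is modeled only as that single
retro-conversion step (and its n-6 mirror), not as general peroxisomal
shortening, because that is the step the pathway actually uses. Enzyme
names on elongation edges (Elovl5 up to C22 products, Elovl4 beyond) are
labels, not constraints — paralog capability differences live in the
simulator's efficiency vectors. The very long-chain families included by
default are exactly those attested by the functional assays (the seven
assayed substrates); the seed list is an argument, not a hard-coded claim
about unobserved branches. `enumerate_routes()` lists all simple reaction
paths (≤ 12 steps by default, bounding path explosion) in a
locale-independent label order, and is validated against matrix-power
reachability and path-count oracles.

## What the simulator emulates — and what it does not

`simulate_peak_table()` emulates one culture per substrate: a substrate
pool proportional to supplied concentration × uptake (defaults 0.5 mM for
C18, 0.75 mM for C20, 1 mM for C22 substrates — the chain-length uptake
compensation used in the assays, with linear scaling exposed for
sensitivity tests), steady-state cascade amounts as above, an endogenous
background (abundant C16/C18 species plus a trace ≥ C24 saturated tail
whose composition follows the control profile of the study's tables, about
12/75/9/3/1/0.3 % across 24:0–34:0), and independent multiplicative
lognormal noise per area. Lognormal noise (default cv 0.1, a free choice —
the study reports no variance for its profiles) reflects that GC-MS
responses are positive and roughly multiplicative; `cv = 0` gives exact
recovery. PUFA assays default to single cultures and SFA assays to
triplicates, as in the study design. A steady-state (endpoint) model
rather than a kinetic time-course is deliberate: the assay harvests after
two days and reports endpoint profiles, and the one-shot partition gives
closed-form conversions.

What passing simulator-based tests shows is that the statistics invert the
model they assume. Real chromatograms add everything the simulator omits:
co-eluting peaks, integration error, response-factor differences between
channels, substrate β-oxidation losses, and culture-to-culture biological
variation beyond a common cv — so parameter recovery on synthetic data is
a correctness check, not a validation against instruments.

`simulate_qpcr()` produces Ct values on the standard-curve law
(slope −3.32, intercept 38, Gaussian Ct noise sd 0.15 by default, six
standards over five decades); `make_orf()` builds random ORFs with planted
histidine-box (HxxHH) and C-terminal ER-retention (RxKxx) motifs, biased
away from H/R/K elsewhere so planted motifs dominate, for exercising the
scanner on known ground truth. All generators flow from a single seed and
are byte-reproducible.

## Sequence analyses

`translate_orf()` validates frame, start, terminal stop and absence of
internal stops before translating; the protein length is always
`nt/3 − 1`, so the 969/960/918-nt coding regions of the study yield
322/319/305 residues. `scan_motifs()` reports all (overlapping)
histidine-box hits and those RxKxx hits ending within a C-terminal window
of 7 residues by default — the published description says only "at the
carboxyl end", so the window is a parameter with a default that covers a
motif at the −5 position with slack. `global_identity()` wraps
Needleman–Wunsch (BLOSUM62, gap open 11 / extend 1) and counts identical
positions over all alignment columns, gaps included; note the study's
95 %/90 % paralog identities came from BLASTp, a local-alignment
convention that can differ from the global figure by about a point. Since
equally-scoring tracebacks can differ in column count, identity is
computed on a fixed orientation of the pair so the function is exactly
symmetric. `insilico_pcr()` requires exact primer sites by default; with
mismatch tolerance enabled, the 3′-terminal base must still match, because
a mismatched 3′ end does not prime.

## qPCR quantification

`fit_standard_curve()` regresses Ct on log10(copies) and reports slope,
intercept, r², and efficiency `E = 10^(−1/slope) − 1`;
`ct_to_copies()` inverts it exactly on noise-free data. `relative_index()`
converts each fish × tissue × gene Ct to copies through its gene's curve
and normalizes by β-actin copies in the same sample — a ratio invariant to
global pipetting factors. Undetermined Ct values are treated as missing,
not as zero copies; fish lacking the reference measurement are dropped
with a warning. Tissue comparisons reuse `compare_groups()`.

## Numerical and testing choices

Rounding is half-up everywhere a table value is printed. Degenerate inputs
(no detected substrate or products; no ≥ C24 saturate; fewer than two
replicates per group) raise classed errors rather than returning NaN.
Property-style tests run under fixed seeds at sizes chosen to finish in
seconds while exercising the space well: 200 random efficiency vectors for
the cascade identity, 1000 random assays for cumulative monotonicity, 1000
random proteins against the motif oracle, 28 published columns for the
reconstruction consistency check. The bundled `scripts/acceptance.R`
recomputes the same headline quantities end-to-end from a command-line
seed.

## Known limitations

No chromatogram-level processing (peak picking, integration,
deconvolution) is attempted; inputs begin at peak-area tables. The
conversion statistic cannot distinguish an undetected intermediate from a
saturated step — both can print 100 — without raw areas. Kinetic flux
through the pathway graph is out of scope, as are phylogenetic tree
construction, BLAST searches, reference-gene stability screening and
ΔΔCt-style relative quantification.
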