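---
title: "Quantifying histone H3 tail proteoforms from middle-down EThcD data"
author: "midtail package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying histone H3 tail proteoforms from middle-down EThcD data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midtail)
```

## The measurement and the model

Middle-down proteomics of histone H3 measures the intact 36-residue
N-terminal tail peptide, preserving the combinatorial arrangement of
methylations, acetylations and phosphorylations that bottom-up digestion
destroys. The chemistry `midtail` models is a sortase-tagged, TMT 6-plex
labelled tail: every histidine carries the fixed TMT label
(+229.162932 Da, rebuilt exactly from its 13C/15N-coded elemental
composition), and the C-terminus carries a fixed +76.1001 Da correction
because the searched sequence ends in His while the ligated molecule ends
in Lys + 2,3-diaminopropionamide. The package reproduces that correction
analytically as

$$\Delta_{Cterm} = M(\text{Lys res}) + M(\text{Dap-amide}) - M(\text{H}_2\text{O}) - M(\text{His res}) = 76.10005\ \text{Da},$$

within 1e-4 Da of the stored literal.

```{r masses}
mods <- modificationTable()
mods[, c("name", "abbrev", "delta_mass", "targets", "max_per_peptide")]
ctermCorrectionMass(analytic = TRUE)
```

A *proteoform* is the tail variant (H3.1 or H3.3) plus positioned
variable modifications, written in the field's shorthand
(`H3K14ac/K23ac/K27me2`; unmodified = `H3unmod`). Residue index *i* is
histone residue *i*, so index 4 is H3K4. Mass arithmetic is exact
monoisotopic summation over elemental compositions; adding a placement of
delta *d* changes the proteoform mass by exactly *d*.

### Fragment ions

EThcD produces c/z-dominant backbone fragments. Ion series are computed
as b = prefix residue sum, a = b − CO, c = b + NH3, y = suffix + H2O, and
z as the ETD radical species z• = y − NH3 + H. The choice of z• (rather
than even-electron z) follows the fragmentation chemistry: electron
transfer leaves the charge-reduced radical, which is the species actually
observed in ETD-family spectra. Neutral losses of H2O and NH3 are
enumerated alongside plain fragments (configurable). Complementarity,
tested exhaustively over the 36-mer, pins the constants:
c_i + z•_(n−i) = M + M(H atom).

## Pipeline stages and their parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| fragment tolerance | 15 | ppm | Orbitrap MS2 mass accuracy; inclusive boundary |
| precursor tolerance | 500 | ppm | wide window intended to tolerate isotope-peak selection |
| PEP maximum | 0.05 | probability | high-confidence PSMs only; inclusive |
| delta-mod minimum | 10 | score | localization confidence; inclusive |
| reporters per condition | 2 | count | minimum for a usable condition mean |
| fragment charges | 1..2 | — | low-charge fragments dominate annotatable signal |
| candidate PSMs per scan | 5 | count | mirrors the acquisition's 5-precursor cap |
| reporter window | 125.5–132.0 | m/z | TMT 6-plex reporter region, excluded from fragment matching |

**Annotation.** Each theoretical ion is assigned to its closest observed
peak within tolerance (tie broken toward the higher-intensity peak — an
arbitrary but deterministic rule); a peak then carries all ions assigned
to it, so no peak is double-counted. A match is *confirmed* only when the
spectrum contains a heavy-isotope companion at the annotated m/z plus
1.003355/z. The 13C spacing dominates A+1 envelopes of peptides this
size, so it is the primary check; the 15N spacing (0.997035/z) is also
accepted. Only confirmed, non-reporter annotations enter quantification;
unconfirmed matches are retained in the annotation table for inspection.

**Chimeric apportionment.** Co-isolated positional isomers (same mass,
different placement) share every fragment that does not span a differing
placement. Intensity of shared peaks is divided *equally* among the
proteoforms whose ion sets contain the peak. An evidence-weighted
iterative split would be possible but needs a convergence argument and
brings little at the 2–3 co-isolate depths seen here, so the simple rule
was chosen; it conserves intensity exactly and keeps fractions in the
simplex. A scan with zero confirmed intensity is flagged unquantifiable
and excluded rather than imputed.

**Reporter statistics.** Channels are scaled so every channel's mean over
all PSM-bearing scans equals the maximum channel mean — the standard
isobaric assumption that overall labelled material is equal across
channels, valid when most proteoforms do not change. Normalized
intensities are log2 transformed; per-scan per-channel values (not
per-replicate means) are pooled by proteoform group and condition, the
log2 fold change is the difference of condition means, and significance
comes from a two-sided Welch t-test (the unequal-variance form is the
safer default where group sizes and spreads differ). By default a
chimeric scan contributes its full reporter signal to every proteoform
group it is assigned to; `weightByFraction` instead multiplies the linear
signal by the scan's proteoform fraction before the log transform. Raw
p-values are reported by default, matching the analysis convention the
pipeline follows; Benjamini–Hochberg adjustment is available behind
`adjustP`.

## What the simulator emulates — and what it does not

`simulateExperiment()` emits: 8+ precursors (480–540 m/z window checked,
advisory only); c/z-dominant fragment ion sets of the true proteoforms
with per-ion log-normal base intensities, multiplicative CV noise and
Bernoulli dropout; two-peak binomial-carbon isotope envelopes (13C
abundance 0.0107) so every fragment is confirmable; co-isolation of up to
5 panel members with Dirichlet or fixed mixing fractions; TMT reporters
at base × condition fold change × log-normal noise; uniform chaff peaks;
and PSM rows with passing scores plus decoys that always fail the
filters. Everything is deterministic under the design seed.

Deliberately *not* modelled: chromatography and retention time, MS1,
fragment-level interference between non-isobaric precursors,
reporter-channel isotope impurity bleed, and per-scan correlated reporter
noise (a shared per-scan intensity factor would make the pooled t-test
conservative; the generator keeps channel noise independent so the null
simulation measures the test's nominal size). Passing tests on this
generator therefore validate the *estimators* — conservation,
apportionment, normalization algebra, test calibration — not
instrument-specific artefacts.

Two generator conventions matter for interpreting results:

* **Unique-only isomer fixtures.** The `"isomer-pair"` fixtures emit only
  ions unique to each co-isolate. With shared ions present, the equal
  split biases per-scan fractions toward 1/|set| — that bias is a
  property of the method itself, not an implementation defect — so the
  fixtures isolate the apportionment arithmetic, which then recovers the
  designed 0.7/0.3 mixture exactly in the noise-free case.
* **Symmetric fold-change splits.** Designed fold changes are applied as
  2^(±log2FC/2) on the two conditions. An asymmetric panel (all changes
  on one side) would shift channel means and thus leak a normalization
  offset into every estimate — again a property of mean-anchored channel
  normalization; the grid fixture also carries 90 null groups as the
  anchor, mirroring the assumption that most proteoforms are unchanged.

## Numerical choices and degenerate inputs

Tolerance comparisons are inclusive (`<=`) at both the ppm boundary and
the PSM score thresholds. Coincident simulated peaks are merged at 1e-5
m/z, the centroiding grain. Peaks arriving unsorted are sorted with a
warning; empty spectra, empty PSM tables and header-only files propagate
as empty results rather than errors; a channel with no usable signal is a
hard error naming the channel (normalization would otherwise divide by
zero silently). Unparseable PSM rows are collected in a rejects table
with reasons, never dropped silently. Proteoform keys canonicalize to
position-sorted order, so formatting after parsing is idempotent.

## Problem sizes

The bundled studies run at sizes chosen to make sampling error small
relative to the effects under test while staying desk-scale: 1000 mixed
chimeric scans for the conservation checks, 200 scans for the noisy
mixture recovery (mean absolute error ~0.03 against a 0.05 bound), 120
proteoform groups × 10 scans for fold-change recovery (RMSE ~0.09
against a 0.2 bound), and 200 null groups for the type-I check, whose
pass band is the binomial 99% interval around 0.05.

## Limitations

Only the two H3 tail variants are modelled (no H4/H2A/H2B); no intact
mass deconvolution or fine-structure isotope computation; no FDR
re-estimation or PSM rescoring; no isobaric impurity correction matrix;
channel-to-condition layouts across multiple 6-plex sets are the user's
responsibility via the configuration. The equal shared-ion split and the
full-reporter-per-group default are documented conventions where the
underlying analysis admits more than one reading; both alternatives that
were considered are either implemented behind a flag
(`weightByFraction`) or noted above.
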