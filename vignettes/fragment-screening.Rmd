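---
title: "Screening amyloid-beta fragments for fibrillogenesis inhibition: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening amyloid-beta fragments for fibrillogenesis inhibition: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragscreen)
```

## The problem

Aggregation of the 42-residue amyloid-β peptide (Aβ~1–42~) into cross-β
fibrils is central to Alzheimer's disease, and short Aβ-derived peptides can
interfere with it. A systematic screen slides seven overlapping 10–12 residue
windows (P1–P7) along the Aβ~1–42~ sequence, follows each peptide and each
parent+fragment mixture spectroscopically over ~100 h, and asks two
questions: which fragments themselves form β-sheet aggregates, and which
suppress fibrillogenesis of the full-length peptide.

`fragscreen` implements the computational side of that screen as a tidy
pipeline: sequence-derived properties, reduction of four spectral modalities
(ThT fluorescence, 90° light scattering, FTIR, CD) to interpretable
summaries, the inhibition-percentage statistic, the Phe→Tyr resonance energy
transfer (RET) difference-spectrum procedure, and a seeded synthetic-data
generator that stands in for the (undeposited) raw spectra so that every
stage is testable against known ground truth.

## Sequence properties

Net charge is the Henderson–Hasselbalch sum over ionizable sites: a basic
site with dissociation constant $pK_a$ contributes $1/(1+10^{pH-pK_a})$, an
acidic one $-1/(1+10^{pK_a-pH})$. The theoretical pI is the pH where this
sum crosses zero, found by bisection on [0, 14] (tolerance $10^{-3}$ pH,
reported to two decimals, matching how such values are conventionally
printed).

The default pKa set is the Bjellqvist table as used by the ExPASy ProtParam
service, including its residue-specific N-terminal pKas (e.g. 7.59 for an
N-terminal Ala, 7.50 otherwise) and the raised C-terminal pKa when the last
residue is Asp (4.55) or Glu (4.75). With free termini this reproduces
ProtParam's printed values for the fragment windows:

```{r}
peptide_properties(fragment_windows(abeta42_sequence()))[, c("name", "sequence", "pI")]
```

Two conventions deserve care. First, the synthesized screening fragments are
N-acetylated and C-amidated, which removes the terminal charges; published
pI values for such peptides are nevertheless computed with free termini (the
ProtParam convention). `free_termini = TRUE` is therefore the default, with
`FALSE` available for the chemically accurate capped case — in which a
peptide without ionizable side chains of both signs has no pI and the
function says so rather than returning a boundary value. Second,
non-standard residue codes are rejected outright: silently skipping them
would corrupt charge sums.

## Spectral data model

All spectra live in one long format: columns `sample_id`, `modality`,
`axis_kind` (`wavelength_nm` or `wavenumber_cm1`), `replicate`, `time_h`,
`axis`, `intensity`. Files carry a small `# key: value` header and either a
long table or a wide one (one column per time point). Doubles are written
with 17 significant digits and parsed with base R's correctly rounded
parser, so files round-trip bit-exactly.

Three operations are shared by everything downstream:

* **`band_average()`** — the arithmetic mean over a closed axis window.
  Every reduction in the assay is such a window: ThT fluorescence 475–485
  nm, scattering 550–555 nm, RET 270–290 nm (Phe) and 300–320 nm (Tyr).
  Window ends are inclusive; whether the original windows included their
  endpoints is not documented anywhere, and the closed-interval choice is
  the one that reads naturally and tests cleanly.
* **`savitzky_golay()`** — least-squares polynomial smoothing, default 13
  points. The polynomial order is not documented in the source procedure;
  order 2 (the classical smoothing table) is the default and configurable.
  Edges are reflect-padded by default (`edge = "fit"` switches to the
  asymmetric least-squares fits). The axis must be uniform to within
  $10^{-6}$ of its span, otherwise the function instructs resampling rather
  than silently mis-weighting.
* **`combine_spectra()`** — pointwise linear combination; mismatched grids
  are linearly interpolated onto the union of axis points over the
  overlapping range. Instrument grids are dense relative to every band
  width used here, so linear interpolation error is negligible.

## Secondary structure

**FTIR.** The amide-I region (1600–1700 cm⁻¹) is decomposed into four
Gaussian component bands: β-sheet near 1627 cm⁻¹, unordered near 1647,
α-helix near 1658, β-turn near 1672. Centres may float ±4 cm⁻¹ (spanning
the paired positions 1627/1623, 1647/1640, 1672/1670 observed across
peptides) and FWHMs are bounded to 8–40 cm⁻¹. Amplitudes are non-negative:
the fit is seeded by non-negative least squares at the nominal shapes and
refined by box-constrained Levenberg–Marquardt, with a final non-negative
amplitude re-solve at the fitted shapes. Structure fractions are component
areas over total fitted area, hence invariant to intensity scaling. A fit
whose relative RMS residual exceeds 10% is flagged (not raised), as is an
all-zero input. Band shape is Gaussian because only positions are known;
nothing in the interface precludes swapping the band table.

Known limitation: the unordered/helix pair sits 11 cm⁻¹ apart with ~25 cm⁻¹
widths, so when both are present their individual fractions are weakly
identified under noise (at 1% peak-height noise the mean absolute fraction
error of a fully populated four-band mixture is about 0.05, versus ~0.002
for a two-band mixture of the well-separated 1627/1672 pair). The terminal
acetyl/amide groups of capped fragments add genuine amide signal in the
1650–1638 cm⁻¹ region; this is not corrected for, only noted.

**CD.** Classification is positional, not a basis-set deconvolution,
because that is how far-UV spectra of this kind are read in practice and
because 4-mm-cuvette data are unreliable below 200 nm: a negative extremum
in 215–225 nm together with positive ellipticity at 195–205 nm is called
β-sheet; double minima near 208 and 220–225 nm without the positive lobe,
helix; a dominant negative extremum at 195–203 nm, unordered; anything
else, mixed/turn. Thresholds are relative to the largest absolute
ellipticity, so calls are invariant to positive rescaling.

## Aggregation time courses and the inhibition statistic

`tht_timecourse()` and `scattering_timecourse()` reduce spectral series to
per-replicate (time, value) records via the two windows above. No kinetic
model is fitted in the analysis path — the assay's summary quantity is the
plateau, taken by `window_mean()` as the per-replicate mean over 32–48 h,
with grand mean and across-replicate sample SD (labelled SD; with one
replicate the SD is reported as 0 and flagged).

The inhibition percentage for a fragment is

$$IP = \left(1 - \frac{F^{*}}{F_0}\right)\times 100\%,\qquad
  F^{*} = F_{tot} - c\,F_{frag},$$

where $F_{tot}$ is the plateau ThT signal of the parent+fragment mixture,
$F_{frag}$ that of the fragment alone at its reference concentration,
$F_0$ that of the parent alone, and $c$ (default 0.7) corrects the
fragment-alone signal to its concentration in the mixture (70 µM in the
mixture against a 100 µM pure-fragment reference) assuming fluorescence
linear in concentration. $c$ is a parameter, not a constant: it equals the
concentration ratio of the design being analysed. Negative IPs
(enhancement) and IPs above 100 (over-correction) are reported and flagged,
never clamped — clamping hides assay anomalies.

`ip_pipeline()` applies the plateau reduction to the three time courses and
computes IP per replicate index when replicate counts match (summarised as
mean ± across-replicate SD), falling back to grand means with first-order
error propagation otherwise. Replicates are treated as unpaired independent
experiments. `timepoint_ttests()` reproduces the per-timepoint testing
style used for comparing fragments: a two-tailed two-sample t-test at every
shared time point, summarised as the mean ± SD of the p-values. Student's
pooled-variance test is the default reading of "t-test"; Welch is one
argument away. No multiple-testing correction is applied, matching the
procedure being reproduced.

## The RET difference procedure

Phe→Tyr RET exploits the unusually short Förster distance of this pair,
$R_0 = 13.5$ Å, with transfer efficiency $E = R_0^6/(R_0^6 + r^6)$
(`forster_efficiency()`). Phe emits near 287 nm, Tyr near 310 nm, and
excitation at 220 nm pumps predominantly Phe.

For a peptide pair, spectra of each peptide alone (full concentration) and
of the equimolar mixture (half each, same total) are Savitzky–Golay
smoothed and combined as

$$D = 2\,F_{mix} - F_A - F_B .$$

For a non-interacting pair the mixture is additive and $D \equiv 0$ —
exactly, for any smoothing settings, because the whole procedure is linear.
Donor quenching with acceptor enhancement, $\Delta F_{Phe} < 0$ and
$\Delta F_{Tyr} > 0$ (band averages of $D$ over 270–290 and 300–320 nm),
indicates energy transfer. `detect_ret()` implements exactly this sign
rule; its `noise_floor` defaults to 0 (the bare sign test), and
`ret_noise_floor()` offers a robust floor — $k$·SD (default $k = 3$) of the
pooled ΔF metrics during a baseline period before any interaction has
developed — which is what the package's own validation uses, since a bare
sign test on a true null is wrong ~25% of the time by symmetry. The three
series are matched in time by nearest neighbour within 0.5 h, reflecting
near-simultaneous acquisition. The factor 2 is a stored `scale` parameter
to support unequal mixing ratios. Tyr quenching drift (water exposure
versus sequestration into aggregates) is modelled in the generator but not
corrected in analysis; it cancels in the component-subtraction scheme and
is interpreted qualitatively otherwise.

## The synthetic-data generator

The generator exists so every pipeline stage can be validated against known
ground truth without the original raw spectra. What it emulates, and what
it does not, bounds what green tests mean.

**Kinetics.** Aggregate mass follows the Finke–Watzky two-step model
(continuous nucleation $A\to B$ at rate $k_n$, autocatalytic growth
$A+B\to 2B$ at rate $k_e$), whose closed form

$$W(t) = A_0 - \frac{k_n/k_e + A_0}{1 + \frac{k_n}{k_e A_0}
  e^{(k_n + k_e A_0)t}}$$

reproduces the lag-free saturating shape of the observed ThT curves with
two interpretable rates. Defaults ($k_n = 0.01$ h⁻¹, $k_e = 0.01$
µM⁻¹h⁻¹, $A_0 = 35$ µM) saturate within about a day, as the parent peptide
does. Aggregated mass splits into a fibrillar (ThT-visible) share
`fibril_fraction_max` (default 0.9) and an amorphous remainder seen only by
scattering — encoding the observation that early scattering outruns ThT
because non-fibrillar aggregates form first. Mass balance
(monomer + fibrillar + amorphous $= A_0$) holds to $10^{-9}$.

**Observation.** Each modality reads a concentration through a Gaussian
band profile (unit peak height) plus Gaussian noise: ThT at 480/30 nm
(2 a.u. per µM fibril for the parent; 0.5 for fragments, whose short
aggregates bind far less dye, keeping fragment-alone signals below the
parent's as observed), scattering at 550/40 nm reading total aggregate
mass, Phe at 287/24 nm and Tyr at 310/28 nm. Noise defaults are
homoscedastic (ThT and scattering SD 2 a.u., emission 1 a.u., FTIR 0.004
absorbance — a few percent of typical plateau signals, consistent with the
size of published replicate error bars), with an optional
signal-proportional component; each replicate also draws a 5% amplitude
factor emulating between-experiment variability. Replicate noise streams
derive deterministically from one master seed; changing only the seed
changes noise realisations, never ground truth.

**Designs.** `simulate_mixture()` reproduces the inhibition design (parent
alone at 35 µM, fragment alone at 100 µM, mixture 35 + 70 µM): the mixture
fibril signal is $(1 - i)$ times the parent signal plus the
concentration-scaled fragment signal, with $i$ the true fractional
inhibition, so `ip_pipeline()` should recover $100i$.
`simulate_emission_pair()` drives the mixture's donor band with
$1 - E(t)$ and pays the transferred quanta into the acceptor band times a
yield (default 0.8), with a transient default interaction profile
($E$ peaking at 0.4 around 20 h, width 8 h — hetero-aggregates that form
and later fall apart as partners self-sort). `simulate_amide_series()`
draws area-weighted band sums along a supplied fraction trajectory.

**What is not emulated:** secondary nucleation or fragmentation kinetics,
photobleaching, baseline drift in FTIR, scattering contamination of CD, or
any instrument response beyond additive noise. Passing recovery tests on
this generator therefore demonstrates the correctness and statistical
behaviour of the analysis, not robustness to every artefact of real
spectra.

## Validation scale and numerical choices

The package's own validation uses desk-scale simulation sizes chosen as a
deliberate design point: inhibition recovery over 200 seeds per true level
{0, 0.25, 0.5, 0.8} with 3 replicates on a 9-point time grid; RET power and
specificity over 50 seeds with calls on replicate-averaged metrics against
the baseline-estimated floor; amide-I recovery over 50 seeds. Bisection
tolerance for pI is $10^{-3}$ pH before two-decimal rounding; FTIR fits cap
Levenberg–Marquardt at 200 iterations; exact ties in the dominant-class
call break by the fixed priority β-sheet > turn > helix > unordered, so a
50/50 β/turn spectrum is called β-sheet with margin 0 rather than
arbitrarily.

## Limitations

Beyond those noted above: the pI convention question for capped peptides is
resolved by exposing both modes rather than guessing which one produced any
given printed value; the CD rules are calibrated to clean band shapes and
will return `mixed_turn` for genuinely ambiguous spectra; and fractional
secondary-structure content from the FTIR decomposition is validated only
against synthetic ground truth, since no reference fractions exist for
these peptides.
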