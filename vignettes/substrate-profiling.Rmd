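---
title: "Substrate profiling of membrane transporters by single-cell GC-MS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substrate profiling of membrane transporters by single-cell GC-MS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oometab)
```

## The experiment this package models

A *Xenopus laevis* oocyte expressing a heterologous amino acid
transporter is a single-cell flux assay.  Batches of 12 pooled stage 5/6
oocytes — transporter-expressing and un-injected controls — are
incubated for 0–4 h in a biomimetic medium containing all 20
proteinogenic amino acids, extracted, derivatised (methoximation +
trimethylsilylation) and run on a single-quadrupole GC-MS with a
7-alkane retention-index ladder (C12–C36) and a ribitol internal
standard.  Comparing transporter-expressing oocytes against matched
controls, with both a fold-change and an absolute-difference readout,
yields the transporter's substrate profile in a single physiologically
relevant incubation.

`oometab` contains both halves of that experiment: a synthetic-data
generator that emulates the biology and the instrument, and the
analysis pipeline that recovers substrate profiles from rendered
batches.  Because the generator knows the ground truth, every stage of
the pipeline is testable against it.

## Transport kinetics

Three mechanisms are simulated on a fixed-step grid (explicit scheme,
step 0.01 h; accuracy requirements are only the stated conservation and
monotonicity tolerances, which this scheme meets by construction).

**Symport / uniport.**  Influx of substrate $i$ follows competitive
Michaelis–Menten kinetics over the carrier:

$$v_i = V_{max,i}\,\frac{S_i/K_{m,i}}{1 + \sum_j S_j/K_{m,j}}$$

with $S_j$ the medium concentrations.  Medium depletion is ignored:
2 ml of medium against nanolitre oocyte volumes makes it negligible.
Ion coupling (the Na⁺/H⁺ stoichiometries drawn in transporter cartoons)
is metadata only; electrochemical driving forces are collapsed into
$V_{max}$.

**Antiport.**  Exchangers perform strict 1:1 exchange: the summed
intracellular amount over the transporter's substrate set is invariant.
Exchange relaxes each substrate toward the proportion of its trans-side
saturation, $\pi_i = (S_i/K_{m,i})/\sum_j (S_j/K_{m,j})$, at the
transporter's exchange rate (0.5 h⁻¹ in the fixtures).  Preloading
oocytes with 10 mM of a single substrate for 6 h makes that substrate
the only trans-side species, so it loads while preferred cytosolic
substrates efflux; the subsequent 4 h medium incubation reverses the
flow.  This two-phase protocol is what makes exchangers measurable at
all: in plain incubation an exchanger only redistributes a conserved
total.

**Endogenous drift.**  Oocytes are not metabolically silent.  In every
sample, regardless of transporter, aspartate, glutamine, citrate and
2-aminoadipate rise more than 2-fold over 4 h while the branched-chain
amino acids fall more than 2-fold; glutamate rises more modestly.
Rates are first-order fixture constants chosen to land at 2.5-fold
(rises) and 0.42-fold (falls) at 4 h — the directions and the >2-fold
magnitudes are pinned by observation, the exact rates are not reported
anywhere and are a generator choice.

**Kinetic constants.**  No $K_m$/$V_{max}$ values are printed for the
profiled transporters, so the fixtures carry synthetic constants with
only ordinal meaning.  $V_{max}$ values are derived so each substrate's
competitive uptake is ~200 pmol/oocyte/h (~800 pmol/oocyte over the 4 h
incubation), the scale of robust heterologous overexpression.  The
EAAT1-like anionic transporter uses 150 pmol/oocyte/h: its uptake must
stay small relative to the ~2 mM endogenous anionic pools, since its
defining behaviour is to be invisible in fold-change yet clear in
absolute difference.  The B0AT1-like substrate set omits tryptophan:
at the low tryptophan concentration of the biomimetic medium its
transport is outcompeted below detection, so the ground-truth profile
mirrors what is observable.

## Instrument model

Peak heights are `amount × response factor × lognormal noise` (5% CV
default).  Response factors come in three classes (high/medium/low =
30/15/6 abundance units per pmol); the low class (Arg, Ala, His, Trp,
Cys) is why those five amino acids are loaded at 10× mass in standard
mixes.  Metabolites with several TMS derivatives render one peak per
variant (aspartate 2TMS/3TMS at RI 1421.1/1508.0, serine 2TMS/3TMS);
all other amino acids derivatise predominantly (≥80%) to a single
variant.  Derivatisation chemistry also converts a fixed fraction of
arginine to ornithine and of glutamate/glutamine to pyroglutamic acid;
both by-products are rendered, identified, and retained in all outputs
flagged with their parents.

Retention times derive from the library retention index through a
linear RT↔RI map (0.325 s per RI unit; C12 at 390 s inside a 21-min
program) plus a per-run retention shift — the drift the in-run alkane
ladder exists to correct — and per-peak Gaussian jitter (σ = 1 RI
unit).  Each batch carries one constant column contaminant (present in
blanks) and one contaminant whose height grows linearly with injection
order, so the QC filters have real work to do.

Between-replicate biology is lognormal noise (10% CV) on the initial
endogenous pools, drawn once per replicate and shared across roles:
each experimental repeat is one donor-frog oocyte batch split across
conditions, which is also what makes paired statistics across
replicates meaningful.  The ribitol spike has 2% CV (pipetting
precision).

## Retention-index calibration

The oven program is a single linear temperature ramp, so the
non-isothermal Kovats index is implemented as piecewise-linear
interpolation in retention time between consecutive alkane anchors
(logarithmic Kovats interpolation applies to isothermal runs).  Indices
beyond the C12–C36 ladder are linearly extrapolated from the nearest
segment and flagged; identification never awards the top criterion
tiers to extrapolated indices.

## Peak detection and deconvolution

Detection follows the standard single-quadrupole parameter set: slope
threshold 200 abundance units/scan on a 5-point-smoothed TIC, minimum
height 500, minimum area 1000, minimum width 5 scans, minimum purity
factor 2.  The baseline is a rolling minimum over 51 scans.  Smoothing
is used only to locate apexes and test slopes; height, area and apex
spectra are taken from the raw baseline-subtracted signal so that a
clean peak's height is not attenuated by the smoother.  Peak regions
end where the signal levels off or falls below 1% of the apex.
Symmetry is the smaller/larger half-area ratio about the intensity
centroid (the straddling scan split proportionally), thresholded at 0.5
— the source procedure requires symmetry without quantifying it, so the
number is a documented choice here.  Co-eluting components are
separated by nonnegative least squares of every m/z trace against
unit-height model peaks placed at the region's TIC maxima; the purity
factor of a component is its height over the largest co-eluting
component's height, with a large sentinel when it elutes alone.

## Identification

Three tiers, evaluated per peak against library candidates within an
RI window of 4 units (candidates must also pass a forward-score
admission gate of 600/1000, the "minimum similarity product"):

1. **Criterion 1** — RI within ±3.0 units, ≥4 characteristic library
   ions present, forward score ≥850, deconvolved abundance ≥500,
   acceptable symmetry, and qualifier-ion ratios valid (≥2 ions within
   30% of the library ratio to the quantifier and mean ratio error
   ≤70%).
2. **Criterion 2** — criterion 1 plus confirmation by an authentic
   standard in the same batch (the 21-component amino acid mix).
3. **Criterion 3** — for peaks failing 1–2: reverse (head-to-tail)
   score ≥700 with the two most abundant library ions present.

Scores are weighted cosines with weights $\sqrt{I}\cdot m/z$, scaled to
1000 (forward, over the ion union) or 999 (reverse, restricted to
library ions so contaminating query ions don't penalise).  The weight
exponents are fixed, documented constants; only the self-match and
orthogonality identities and the printed thresholds carry meaning, and
the tests enforce exactly that.  The TMS reagent ions at m/z 73 and 147
sit in essentially every derivatised spectrum and are excluded from all
decisive comparisons.  Whether the two printed score thresholds live on
one scale is unstated in the source; they are treated here as two
separate gates.

## Quality control

* **Ribitol gate**: samples whose internal-standard height deviates
  more than 10% are discarded.  The reference is the batch *median* —
  robust to the very outliers the gate removes; the source does not say
  what the deviation is measured against, so this is a documented
  choice.
* **Drift filter**: a row is removed when its abundance has Spearman
  correlation ≥0.8 with injection order in *every* role with enough
  injections — including QC pools and standards, whose content is
  constant by construction.  Requiring role-independence is what spares
  genuine substrates (which rise only in transporter samples) and
  drifting endogenous metabolites (flat in QC pools).  Rank correlation
  rather than literal monotonicity tolerates noise.  Without any
  non-biological role the filter no-ops with a warning, which also
  makes the QC pass idempotent.
* **Blank filter**: rows whose mean blank signal reaches 10% of the
  mean biological signal are column contaminants.  Blank cells censored
  at the detection floor count as zero here; counting the floor itself
  would delete every low-abundance metabolite.
* **Internal peaks**: ribitol and the alkanes are stripped from the
  analysis matrix; ribitol is kept aside and re-attached to every
  profile as the negative-control row, whose fold-change should sit
  within 1 ± 0.1.

Values below the 500-unit floor are reported *at* the floor with a
censoring flag: they participate in fold-changes (the floor guarantees
a nonzero denominator) but are marked in outputs.

## Profiling statistics

For each metabolite and timepoint, with matched controls in the same
medium for the same time:

* fold-change $FC = \bar T/\bar U$ and absolute difference
  $\Delta = \bar T - \bar U$;
* the **time contrast**: two-sided paired *t*-test on raw transporter
  values between the first and the evaluated timepoint, paired by
  replicate — this drives the `significant` flag (the heat-map
  asterisk);
* the **control contrast**: paired *t*-test of transporter minus
  matched control across replicates at the evaluated timepoint.

A metabolite is called *accumulated* when the time contrast is
significant and either route detects an increase: $FC \ge 2$ (the
conventional two-fold yardstick, the same one used to describe
endogenous drift) or a replicate-consistent positive control contrast
at $p<0.05$ with $|\Delta|$ above the floor.  *Depleted* is symmetric;
everything else is *unchanged*.  The dual readout is the method's
point: fold-change alone misses transporters working against large
endogenous pools (the anionic amino acids), absolute difference alone
misses low-abundance substrates; each route rescues the other's false
negatives.  No multiple-testing correction is applied to the calls
(matching the per-metabolite $p<0.05$ convention of the assay); a
Benjamini–Hochberg column is reported alongside.

With three replicates the paired *t* has two degrees of freedom, so
detection power is real but limited; the fixtures' uptake scale
(~800 pmol/oocyte per 4 h) puts true substrates at non-centrality ~9,
i.e. ≥95% power, while the type-I rate under the simulated null sits at
the nominal 5% (verified over 500 simulated batches in the test suite).

Exchangers are profiled per phase: preload (post-preload vs baseline —
the preloaded substrate must rise, efflux substrates fall) and medium
(post-medium vs post-preload — influx substrates rise, the preloaded
substrate exits), with signs attached only at $p<0.05$.

## Quantification

Calibration is per amino acid from 6-point standard series grouped by
response-factor class, as ordinary least squares of peak height on
amount; curves with adjusted $R^2 < 0.94$ are flagged.  Heights invert
through the curve to nmol, then to pmol/oocyte over the pool size, and
to intracellular concentration over the 365 nL water-accessible volume
($\mathrm{pmol/oocyte} = \mu M \times 0.365$; this identity reproduces
the published endogenous-pool table exactly, which the test suite
checks row by row).  Negative back-calculated amounts are clipped to
zero and flagged — they occur for metabolites whose signal sits below
the bottom of the calibration range, which is honest instrument
behaviour, not an error.

## What the generator does and does not emulate

It emulates: the statistical structure the analysis assumes (matched
controls, paired replicates, multiplicative noise), competitive uptake
and strict exchange, endogenous drift, RI drift and its correction,
TMS-variant and conversion chemistry, response-factor classes,
censoring at the detection floor, and batch artefacts (drifting and
constant contaminants, QC/standard/blank layout).

It does not emulate: real electron-impact fragmentation (spectra are
fixed synthetic stand-ins; identification tests therefore exercise the
decision procedure, not spectral chemistry), membrane potential or ion
gradients, protein-synthesis consumption of amino acids beyond the
aggregate drift, medium depletion, retention-time alignment problems
beyond a linear shift, or LC-MS.  Passing tests show the pipeline
recovers what the model plants under realistic noise; they cannot show
how the pipeline fares against fragmentation artefacts or matrix
effects absent from the model.

## Problem sizes and determinism

Default study conditions are the experiment's own: 12 oocytes per
sample, 3 replicates, timepoints {0, 4} h, 5% instrument CV, 10% pool
CV.  The simulation studies in the tests use 300–500 simulated batches
for error-rate calibration and a handful of fully rendered batches
(~40 injections each) elsewhere.  Every source of randomness flows from
the design seed; a config plus its seed reproduces all outputs
byte-identically, and the batch manifest records both.

## Worked example

```{r example, eval = FALSE}
library(oometab)

cfg <- pipeline_config(design = experiment_design("SNAT2-like", seed = 42))
batch <- generate_batch(cfg$design)
res <- run_profile(batch, cfg)

subset(res$calls, call == "accumulated")
#>           metabolite        call
#> 28           Leucine accumulated
#> 30           Proline accumulated
#> 31           Glycine accumulated
#> 32           Alanine accumulated
#> 33            Serine accumulated
#> 36        Methionine accumulated
#> 40        Asparagine accumulated
#> 41         Glutamine accumulated
#> 48 Pyroglutamic acid accumulated
```

The eight called amino acids are exactly the SNAT2-like fixture's
substrate set; pyroglutamic acid co-accumulates as the derivatisation
product of accumulated glutamine, which is why it is carried in every
heat map flagged with its parents.
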