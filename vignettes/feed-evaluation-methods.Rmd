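---
title: "Methods: digestibility calculus and energy prediction for swine feed ingredients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digestibility calculus and energy prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swinedigest)
```

# The problem

Evaluating a candidate feed ingredient for pigs means answering three
questions: how much of its gross energy the animal can use (digestible and
metabolizable energy, DE/ME), how digestible its phosphorus and amino acids
are after correcting for what the animal itself secretes, and whether cheap
surrogates — in vitro digestion or published prediction equations — can
stand in for the animal trial. `swinedigest` implements this chain for
composition tables of dried food waste sources (fish waste, supermarket
waste, fruit and vegetable waste) and corn, together with a synthetic trial
generator that makes every estimator testable.

# Composition and basis algebra

Compositions are stored as percent by mass (mirroring how feed tables are
printed, which minimizes transcription error) with an explicit basis tag.
Conversion between as-fed and DM bases is exact linear scaling by the DM
fraction, so a round trip is the identity to floating-point precision; the
package asserts 1e-9 relative. A nutrient that was not analyzed is carried
as `NA`, never as zero: a silently zeroed fiber term shifts some energy
predictions by more than 100 kcal/kg, so any consumer that needs the field
fails with the field's name. Amino acids use case-normalized three-letter
codes.

Gross energy can be estimated from proximate composition as
`GE = 4143 + 56·EE + 15·CP − 44·ash` (% DM in, kcal/kg DM out); it enters
the prediction registry as the "calculated GE" variant.

# In vivo calculus

**Marker ratio.** All trial diets carry 0.40% TiO₂. For any nutrient with
concentration `C` (same basis in diet and output),

d = 1 − (Ti_diet / Ti_out) · (C_out / C_diet).

Negative values are legitimate — fibrous feeds can push more of an amino
acid out of the ileum than the diet supplied, via stimulated endogenous
secretion — so nothing is clipped; results carry flags instead.

**Diet and ingredient energy.** DE is GE intake minus fecal energy, ME
additionally subtracts urinary energy, both per kg of DM intake. Both a
total-collection and a marker-ratio estimator are provided; the default is
the marker ratio, matching the marker's presence in every diet, and the two
agree to numerical precision on mass-balanced records (urinary energy is
always total-collection, as urine carries no marker). Ingredient energy
uses the difference method: with the test diet replacing corn
(66.9%/96.9%) at 30% inclusion,

DE_ingr = [DE_test − (0.669/0.969)·DE_basal] / 0.30,

crediting corn at its basal-diet value and treating the constant 3.1%
mineral/vitamin base as energy-neutral. Per-pig ingredient estimates are
formed against the basal-diet *mean*, and the experimental unit is the pig
throughout: digestibilities are computed per pig and then averaged, never
from pooled concentrations. Feed intake follows the allowance rule of three
times maintenance, 197 kcal ME per kg BW^0.60. Adaptation/collection-period
lengths are not modeled; records are per collection period.

**Standardization.** Apparent total tract digestibility of P is corrected
with a basal endogenous loss, default 190 mg/kg DM intake, as
`STTD = ATTD + 100·(loss/1000)/P_diet` with `P_diet` in g/kg DM. The loss
is a configurable argument, not a constant, so other species or assumption
sets can be explored. Ileal amino acid digestibility is standardized the
same way with endogenous flows (g/kg DMI) estimated from a nitrogen-free
diet, `flow = C_digesta·Ti_diet/Ti_digesta`, averaged over pigs; the SID
correction divides by the dietary amino acid in g/kg DM, the same
normalization the marker ratio uses. Both corrections are additive and
nonnegative, so standardized ≥ apparent is an invariant the tests check on
every simulated dataset. A requested amino acid with no endogenous entry is
an error, not a silent zero.

# In vitro assembly

The three-step procedure contributes two DM-disappearance measurements
(pepsin–pancreatin hydrolysis; fecal-inoculum fermentation of the
hydrolysis residue) combined as `DMD = IVHDMD + (100 − IVHDMD)·IVFDMD/100`.
The combination is written in this percent-normalized form deliberately:
the naive product of two percentages exceeds 100 for any nonzero inputs,
while the normalized form satisfies the endpoint identities (fermentation
of nothing adds nothing; complete fermentation reaches 100).

In vitro total-tract DE is the energy that disappeared in hydrolysis plus
the VFA credit from fermentation:

DE = GE_sample − f_res·GE_residue + E_VFA,

with `f_res` the residue mass fraction, so every term is per kg of original
sample DM (the residue's energy *density* must be mass-weighted for the
units to agree). VFA energy uses 209, 365, 522 and 678 kcal/mol for
acetate, propionate, butyrate and valerate. Assays report mmol/L of
supernatant; since the mapping to moles per kg of sample depends on bench
geometry, the conversion volume (default 30 mL over 200 mg DM) is an
explicit argument, not an assumption. Gas-production curves are stored as
raw (hour, mL) data only — no kinetic model is fitted. In vitro OM
digestibility (OMdv), the input to the fourth equation family, is likewise
an input field: it comes from the bench, never from this package.

# Prediction equations and the accuracy rule

The registry holds 19 affine equations in three families whose unit
conventions differ and are easy to confuse: the chemical-composition family
takes g/kg DM, the stepwise-regression family % DM, and the in vitro
family g/kg DM with output in MJ/kg DM converted at 1 MJ = 238.834 kcal.
The conventions were fixed by requiring the registry to reproduce the
published prediction tables from the packaged composition fixture; a test
recovers every coefficient numerically from finite differences, so a
transcription error cannot hide behind the unit handling.

Two reproduction caveats are handled explicitly rather than silently:

* The fish-waste rows of the chemical-composition family are reproducible
  only with the NDF term zeroed (5,234 vs 5,065 kcal/kg DM for the first
  equation). Analyzed fish-waste NDF (3.81% as-fed) is small but not zero,
  and detergent-fiber assays are ill-defined on animal products. The
  package defaults to analyzed NDF for every ingredient and offers an
  explicit `ndf_zero` override, flagged in the output notes.
* The published ME values of the two calculated-vs-analyzed-GE variants
  appear transposed relative to their definitions, and one fish-waste ME
  value is not derivable from its defining DE minus 0.68·CP. The equations
  are implemented as defined; by-construction identity with the DE parents
  is asserted, and these cells are excluded from exact-reproduction tests.

Full precision is kept internally; rounding to the nearest kcal happens
only in table writers. With full-precision DM conversion four published
cells differ by exactly 1 kcal (the source evidently rounded DM-basis
inputs to two decimals first), so reproduction is asserted to the printed
precision of 1 kcal.

The accuracy rule classifies a prediction as accurate when it falls within
`mean ± t(0.975, n−1)·s/√n` of the per-pig in vivo estimates (n = 9
pigs/treatment). The Student-t margin is a design choice — the source does
not print its margin formula, and its pooled SEM is inconsistent with the
printed per-ingredient margins — so the assessment function also accepts a
margin directly, letting published bounds be used verbatim. Narrowing the
margin can only turn "within" into "outside"; the tests check this
monotonicity and the bound identities.

# The synthetic generator

Animal data cannot ship with a package, so the in vivo population values
serve as simulation truths: ingredient DE/ME, DM digestibility, ATTD of P,
and per-amino-acid AID, with basal endogenous flows derived from the
fish-waste standardized-minus-apparent gap (e.g. 0.50 g Lys/kg DMI, in the
range nitrogen-free studies report). Diet-level truths come from the same
contribution algebra the difference method inverts, which makes the
noise-free round trip exact by construction — that exactness (asserted at
1e-9) is the point: it certifies the estimator algebra, not the biology.

Records are generated by exact mass balance (marker intake = marker output;
energy in = energy absorbed + fecal + urinary) and then perturbed with
multiplicative lognormal noise of fixed CV on *observed concentrations*
(fecal/digesta GE, Ti, nutrient concentrations) — assays are positive and
CV-scaled, which a lognormal captures and an additive Gaussian does not.
Defaults: marker CV 5%, GE assay CV 2%, concentration CV 5%; cohort 9
pigs/diet with BW ~ N(16.37, 1.9²) kg; ileal digesta DM flow 0.25 kg/kg
DMI (typical of cannulated pigs on semi-purified diets; it cancels from
every estimator). Each record type draws from its own seeded stream, so a
scenario with a fixed seed is bitwise-reproducible.

Monte-Carlo calibration (500 replicate trials at 5% CVs, about a minute of
compute) shows recovered ingredient DE unbiased to <1% and mean recovered
AID within 2 points of truth; the empirical coverage of the 95% t-interval
sits slightly below nominal because per-pig ingredient estimates share the
basal-diet mean, a correlation the interval ignores — the same caveat
applies to the real design.

What the generator does *not* emulate: growth or day-to-day autocorrelation
within the collection period, feed refusals and spillage, analytical
interference between nutrients, or any systematic (non-multiplicative)
assay bias. Passing recovery tests therefore validate the estimators under
clean assay-noise assumptions; they do not certify the published animal
values themselves, which enter only as scenario truths.

# Degenerate inputs and numerical choices

Zero DM intake, zero marker in output, zero dietary concentration and an
out-of-range residue mass are hard errors with named messages. A fecal
marker concentration below the dietary one is a data-sanity *warning* (the
record may still be wanted for diagnosis). Prediction outputs below zero
(possible for low-CP/EE feeds under one regression) are returned with a
note, not suppressed. Ties and ordering: accuracy reports are sorted by
absolute signed error; verdicts are order-invariant.

# Limitations

No net-energy system, nitrogen balance, true (vs standardized) ileal
digestibility, diet-specific endogenous losses, gas-production kinetics, or
mixed-model treatment comparisons: the package reproduces the evaluation
calculus, not the inferential statistics around it. The in vitro module
computes with bench measurements; it does not simulate enzyme chemistry.
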