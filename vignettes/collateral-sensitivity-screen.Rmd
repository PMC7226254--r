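---
title: "Methods: simulating and analysing a collateral-sensitivity viability screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a collateral-sensitivity viability screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The screen being modelled

A resistance mutation that removes a drug's binding site sometimes creates a
new, targetable weakness — collateral sensitivity. The screen this package
models searches for such compounds against the C481S mutation of BTK, which
abolishes covalent ibrutinib binding. The cellular reporter system is a pair
of isogenic Ba/F3 lines: Ba/F3 cells need IL3 unless transformed by an
active oncogene, so overexpressing BTK with the activating E41K mutation
makes their survival in IL3-free medium a direct readout of BTK activity.
One line carries BTK^E41K^ (ibrutinib-sensitive, GFP-tagged), the other
BTK^E41K-C481S^ (ibrutinib-resistant). A kinase-inhibitor library is tested
on both lines at 100 nM and 1 µM in duplicate in 384-well plates; after
48 h, living GFP^+^ cells are counted from 5 fluorescence fields per well,
viability is expressed as percent of the DMSO vehicle wells, and each
compound receives a differential score at each dose:

$$d = \mathrm{viability}_{E41K\text{-}C481S} - \mathrm{viability}_{E41K}.$$

Plotting d at 100 nM (x) against d at 1 µM (y) splits the library into
quadrants: compounds selectively active against the sensitive line fall
upper-right (the expected home of BTK inhibitors, which validates the
design), and collateral-sensitivity compounds fall lower-left. Candidates
with clearly negative d at at least one dose are then confirmed on a wide
dose range by per-line IC50 estimation.

No raw screen data are publicly deposited, so the package is driven
entirely by a synthetic-data module whose structure mirrors the real assay.
Every downstream stage — image quantification, normalization, scoring,
triage, confirmation — is therefore testable against known ground truth.

## The generative model

**Compound library.** Each of the 590 simulated compounds belongs to one of
five effect classes, with exact class counts obtained by largest-remainder
rounding of the mixture proportions. Per-line kill at dose $x$ follows a
four-parameter log-logistic curve with floor 0 and ceiling `max_kill`:

$$\mathrm{kill}(x) = \mathrm{max\_kill}\cdot\frac{x^{h}}{x^{h} + \mathrm{IC50}^{h}}.$$

The sigmoidal survival curves the assay produces do not come with a stated
functional form; the 4PL is the standard choice in high-throughput
pharmacology and matches the fitting stage, so round-trip recovery is
meaningful. Class parameter ranges (IC50s in nM, sampled log-uniformly):

| class | IC50 sensitive | resistant/sensitive ratio | max_kill |
|---|---|---|---|
| `btk_inhibitor` | 20–150 | 30–300 | 0.85–1 |
| `pi3k_inhibitor` | 100–500 | 2–6 | 0.7–0.95 |
| `cytotoxic` | 50–2000 | 1 (equal) | 0.85–1 |
| `collateral_sensitive` | 30–300 × resistant | resistant 20–100 nM | 0.85–1 |
| `inert` | — | — | 0 |

Hill slopes are uniform on 0.8–1.5 throughout. The default mixture
(2% BTK-like, 4% PI3K-like, 15% cytotoxic, 0.5% collateral-sensitive, rest
inert) gives 12 BTK-like and 24 PI3K-like compounds in 590 — the order of
magnitude a commercial kinase-inhibitor library contains — plus 3 spiked
collateral-sensitivity compounds. The real library contained no confirmed
collateral hit; the spike exists so the hit-calling stage has a positive
control with known truth.

**Plates and counts.** Each plate carries one line at one dose: column 1 is
DMSO vehicle, column 24 holds the positive controls (ibrutinib rows A–H,
pentamidine rows I–P, at 1 µM), columns 2–23 hold compounds. With 590
compounds and 352 compound wells per plate, the default screen is 16
plates (2 lines × 2 doses × 2 replicates × 2 plates). A well's expected
count is `cells_seeded × growth_factor × (1 − kill)`; 10,000 cells are
seeded and the growth factor is 8 (roughly three doublings in 48 h — Ba/F3
divide every 13–16 h; its exact value is irrelevant because it cancels in
normalization). Well noise is multiplicative lognormal with configurable
CV, default 0.1 — typical inter-well variability for a cell-count readout,
where variance scales with the mean and counts stay positive. Counts are
kept continuous so that the noise-free configuration closes exactly:
normalized viability then equals $100(1-\mathrm{kill})$ to machine
precision, which several tests exploit. Plate-edge effects are not
simulated.

**Field images.** Wells can also be quantified through rendered images:
cells are non-overlapping bright ellipses (semi-minor axis 2–3.5 px, axis
ratio ≤ 1.3, ~600 intensity units) over a background of 100 ± 8 units on
the 16-bit scale, placed by rejection sampling with a guaranteed background
gap, at least one pixel clear of the border. Default densities stay below
half the jamming limit of sequential placement, so rendering never stalls.
The renderer returns ground-truth centroids, giving segmentation an exact
oracle. Real microscopy differs in ways the renderer does not model —
overlapping and out-of-focus cells, debris, uneven illumination — so
passing the oracle shows the counting pipeline is correct on its stated
object model, not that it matches a commercial reader on real plates.

**Competition assay.** The two-clone competition experiment that validates
oncogene addiction is modelled as two exponentially growing populations,
integrated with `deSolve::lsoda` at tight tolerances (rtol 1e-12). With
IL3 both clones grow at 0.7/day from a 49% GFP^+^ mixture, so the
composition is stable at 49%; without IL3 the wild-type clone decays at
0.40/day while the activated clone grows at 0.48/day, putting the day-3
GFP^+^ fraction at 93.1% — the two figures the competitive assay reports.
The closed form
$f(t) = f_0 e^{r_m t}/(f_0 e^{r_m t} + (1-f_0)e^{r_w t})$
is kept in the package only as the analytic cross-check.

## Image quantification

The described readout names three detection parameters — area, roundness,
intensity — but the instrument's algorithm is proprietary. The package
implements the simplest pipeline consistent with those parameters: a global
intensity threshold, 8-connected component labelling, then per-object
filters. Choices worth knowing:

* **Threshold.** Default is robust-automatic, `median + k·MAD` of the whole
  field with `k = 6` and a strict `>` comparison, so a noise-free uniform
  background (MAD = 0) stays background. A user-supplied absolute threshold
  uses `>=`. Both are scale-invariant in the auto case, which makes counts
  robust to 8- vs 16-bit input.
* **Labelling** is iterative 8-neighbour minimum-label propagation, written
  in-package because the required 8-connectivity is not available in the
  installed image stack's labeller. It converges in at most
  one iteration per pixel of component diameter — a dozen for these cells.
* **Roundness** is the isoperimetric ratio $4\pi A/P^2$ with a crack-length
  perimeter (count of exposed 4-edges), clipped to [0, 1]. Crack-length
  perimeters overestimate smooth contours: any convex digital shape has
  $P = 2(w+h)$ of its bounding box, so an ideal digital disk scores
  $\pi^2/16 \approx 0.62$, a square $\pi/4 \approx 0.79$, and a 1-px line
  far less. The default `min_roundness = 0.4` therefore accepts compact
  blobs and rejects linear debris; it is not comparable to roundness
  values from polygonal-perimeter software.
* **Area filter** 10–500 px at default rendering scale; **border-touching
  objects are excluded** by default, as partial objects bias counts; the
  renderer never places cells at the border, so oracle equivalence is
  unaffected. "Living cells" is operationalised as filter-passing GFP^+^
  objects — the described assay has no separate live/dead channel.
* Whether the original instrument used intensity as a detection seed or
  only as a filter is unknowable from the assay description; both roles are
  exposed (`intensity_threshold`, `min_mean_intensity`) without any
  fidelity claim.

## Screen analysis

Normalization is per plate × line stratum: each well is divided by the mean
of its own plate's vehicle wells. Whether the original screen anchored per
plate is unstated; per-plate anchoring is the safe choice against plate
effects, and with one line and dose per plate it is also the finest
stratification available. Vehicle wells average exactly 100 per stratum by
construction — a fixed point the tests assert. Viability is deliberately
not capped at 100: capping would break the antisymmetry of d.

d is computed on replicate-mean viabilities (means of duplicates); for the
arithmetic mean the other order (per-replicate d, then average) coincides,
but the choice is fixed and recorded here. Zero d counts as non-negative in
quadrant assignment, making the quadrant map total and deterministic.

The triage rule "more pronounced activity on the resistant line at at
least one concentration" needs a numeric threshold to be operational; none
is stated for the original screen. The default is d ≤ −20 percentage
points at ≥ 1 dose, configurable. At the default noise level (CV 0.1,
duplicates) the SD of d for a null compound is ≈ 10 points, so −20 sits at
2 SD: a 590-compound screen yields a few dozen candidates, mostly noise —
deliberately permissive, like the original triage of 11 drugs, because the
confirmation stage is the real filter.

Plate QC uses the Z′ factor,
$z' = 1 - 3(\sigma_{veh} + \sigma_{pos})/|\mu_{veh} - \mu_{pos}|$,
computed from the pentamidine wells only: ibrutinib is intentionally
inactive on the resistant line, so pooling both controls would make z′
meaningless on half the plates. Ibrutinib wells stay on every plate as the
mutation-specific sentinel. Plates below z′ = 0.5 are flagged, never
dropped. At default noise, simulated plates run z′ ≈ 0.5–0.75.

## Dose–response confirmation

Candidates are re-tested on 8 log-spaced doses (1 nM–100 µM, bracketing
both reference IC50s), triplicate, on both lines, and fitted with
$v(x) = bottom + (top-bottom)/(1+(x/\mathrm{IC50})^{h})$ on log dose by
Levenberg–Marquardt (`minpack.lm`). The IC50 reported is the curve's
inflection (relative IC50), which stays well-defined when the maximal
effect is partial. Initialisation takes top/bottom from the data extremes
and the IC50 from the dose nearest the half-range; three additional
log-spaced IC50 starts guard against local minima. A fit is declared
unconverged — reported, not an error — when the optimiser fails, when the
fitted amplitude `top − bottom` is under 10 viability points (otherwise
flat inert responses get fitted to pure noise and produce arbitrary
"IC50s"), or when the fitted IC50 leaves the tested dose range. The
confirmation call uses the resistance ratio IC50~resistant~/IC50~sensitive~
with a 10-fold threshold, motivated by the ~100-fold separation of the
reference ibrutinib scenario (100 nM vs 10 µM) while leaving headroom for
fit error; `ratio < 1/10` confirms collateral sensitivity.

## Reproducibility and problem sizes

Every stochastic stage draws its seed from a master seed through a fixed
affine splitting rule (`stage_seed()`), so stages are independently
reproducible and two runs with the same configuration produce
byte-identical CSV outputs (asserted in the tests, and recorded as MD5
checksums in the run manifest). The test suite and the analysis scripts
use the full 590-compound screen (6,144 wells) for scoring stages, 200
rendered fields plus one 2,000-cell well for the segmentation oracle, 50
replicate fit pairs for IC50 recovery, and 100 random parameter sets for
the competition closed form — sizes chosen to exercise the full design
while keeping a complete run in minutes on a laptop.

## Known limitations

* The effect-class parameter ranges are plausible inventions, not fitted to
  any measured compound; conclusions about real pharmacology cannot be
  drawn from the simulation.
* The renderer's object model (non-overlapping ellipses, flat background)
  understates real imaging difficulty; segmentation accuracy on real
  plates will be worse than the oracle suggests.
* Growth is a single deterministic factor per line; no growth-rate
  difference between the two lines, no edge effects, no per-plate batch
  effects (an edge-effect option would slot into `simulate_plate` but is
  intentionally not simulated by default).
* The stereochemistry wrinkle reported for the racemate form of ibrutinib
  in the original screen has no counterpart in the simulation.
* IC50 uncertainty is not propagated into the confirmation call (no
  bootstrap CIs); the ratio threshold absorbs fit error instead.
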