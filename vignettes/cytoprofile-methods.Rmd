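---
title: "Cytological profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cytological profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoprofile)
```

## The problem and the pipeline

High-content screening (HCS) treats cells in multiwell plates, images them
by automated fluorescence microscopy, and quantifies each cell across a set
of stained markers. A treatment's *cytological profile* is the vector of
control-normalized feature changes it induces; treatments with similar
profiles tend to share a cellular mechanism, so clustering unknown samples
against an annotated reference-compound library predicts their mode of
action (MoA). cytoprofile implements that pipeline end to end:

1. **simulate** — seeded 384-well screens with known phenotype ground truth
   (or: real per-cell tables / plate images supplied by the user);
2. **segment & extract** — nuclei segmentation and per-cell compartmental
   intensities from the nuclear-stain channel and co-stained markers;
3. **profile** — per-well aggregation, in-plate control subtraction, and
   normalization of feature differences into scores in $[-1, 1]$;
4. **cluster & assign** — Pearson-distance UPGMA over fractions plus
   references, tree cut, majority-label MoA calls;
5. **endpoints** — percent-of-control cytotoxicity, DNA-content cell-cycle
   fractions, in-plate-normalized fold changes, Student's *t* statistics.

## The scoring model

For feature $f$ of sample $s$ at dose $d$, replicate wells are averaged
first, then the in-plate untreated control mean (same plate, same staining
panel) is subtracted:

$$\Delta_{s,d,f} = \overline{x}^{\,\mathrm{treated}}_{s,d,f} -
  \overline{x}^{\,\mathrm{control}}_{f}.$$

HCS profiling conventionally reports feature scores on a [-1, 1] scale
without a canonical definition of the map from differences to that range,
so the normalization was a genuinely open design point. The default here is **screen-max scaling**,

$$\mathrm{score}_{s,d,f} = \Delta_{s,d,f} \big/ \max_{s',d'} |\Delta_{s',d',f}|,$$

chosen because it reproduces the stated range exactly, is parameter-free,
and guarantees that each feature's most deviant sample scores exactly
$\pm 1$. Its cost is that scores are relative to the screen's extremes, so
they are comparable within a screen, not across screens. A bounded robust
alternative, `robust_z_tanh` ($\tanh(z/3)$ with $z$ a MAD-based robust
*z*-score against the control wells), is selectable in
`compute_feature_scores()`; it is screen-independent but saturates slowly
and does not attain the bound. Whether normalization runs per screen
(default) or per plate is also selectable (`per_plate`); the per-screen
default fits the usual workflow in which every plate carries its own
control baseline but all samples share one joint heat map.

Features whose differences are all zero score 0 (no division by zero), and
QC-excluded entries stay missing (`NA`), never zero. A sample missing more
than 25% of its panel features is dropped before clustering
(`drop_incomplete_profiles()`): correlation over too few shared features is
noise.

## Feature panels

The **core panel** has exactly 21 features from 12 markers: cell count,
nuclear area and integrated DNA intensity from the DNA stain; nucleus and
cytoplasmic-ring mean intensities for ER, lysosome, membrane, mitochondria,
NF-kB, actin and tubulin; nucleus-only means for p53, caspase-9,
cytochrome c and gamma-H2AX. The staining panels name 11 distinct markers;
gamma-H2AX — assayed separately as the DNA-damage readout — was adopted as
the twelfth core marker so a 21-feature/12-marker panel is realizable from
the markers the screen actually measures. The **full panel** (135 features)
adds distribution statistics (sd, median, MAD, 90th percentile) per marker
and compartment, nucleus:ring ratios, and the five cell-cycle phase
fractions. Both panels are ordinary data frames and editable.

## The synthetic-data generator

The generator emulates the screen the analysis expects: 3 plants x 28 SPE
fractions = 84 samples, doses (0, 1.56, 3.12, 6.25, 12.5, 25, 50) ug/ml,
quadruplicate wells, four staining panels, 16 medium-only control wells per
384-well plate, and a 735-compound reference library. Each fraction carries
a ground-truth phenotype: an MoA class (inert with probability 0.5,
otherwise one of nine active classes) and an amplitude uniform on
$[0.5, 1]$.

Every dose-dependent quantity uses one parametric family, the Hill curve
$e(d) = (d/\mathrm{EC}_{50})^h / (1 + (d/\mathrm{EC}_{50})^h)$: survival is
$1 - e$ with the class's kill EC50 (cells per well are Poisson around
$2000 \times \mathrm{survival}$; 2,000 is the seeding density, used as the
imaged-count expectation in the absence of a reported per-well count), and
feature shifts, cycle shifts and assay inductions scale with $e$ using the
class's own effect EC50 (default $0.6 \times$ kill EC50 — effects are
assumed to precede frank cell loss).

Two granularities exist. The **well-level** generator draws each well's
feature value directly as
$\mu_f \,(1 + 0.6\, a\, s_f\, e(d)) \times \mathrm{LogNormal}(\mathrm{cv}=5\%)$,
where $\mu_f$ is the control expectation, $a$ the amplitude and $s_f$ the
class's score-space effect direction (entries in $[-1,1]$, pairwise class
correlations kept below 0.5 so classes are separable; `cell_count` and
`nuclear_area` entries of cytotoxic classes forced negative for coherence
with the kill curve, and the count feature itself follows survival, not
$s_f$). The **cell-level** generator draws individual cells — phase from
the control mixture (3% low, 60% G0/G1, 22% S, 13% G2/M, 2% high; a
plausible unperturbed adherent-culture profile) shifted toward the class
target; DNA content per phase (truncated normal peaks at 2N and 4N with sd
0.15N/0.20N, S uniform across the S bin, sub-2N and super-4N tails); areas
and marker intensities as mean-preserving lognormals. Each phase's content
distribution is supported inside its classifier bin, so planted phase
fractions are recoverable to binomial error by construction; DNA
measurement noise is off by default (`dna_noise_cv`) because boundary
leakage would otherwise bias S-phase counts asymmetrically.

What the generator does **not** emulate: optics (PSF, illumination fields),
plate-edge and liquid-handling artifacts, batch effects between plates,
texture/shape features, and biologically realistic covariance between
markers beyond the single class direction. Passing tests therefore show the
*computations* are correct and well-calibrated under the stated noise
model — not that the pipeline is robust to every artifact of real plates.

## Imaging

Segmentation is a transparent stand-in for commercial compartmental
analysis: global threshold, hole filling, distance-transform watershed,
then size (default 20–5000 px) and border validity filters; a well needs
500 valid objects to pass QC. The default threshold is **not** plain Otsu:
with bright G2/M and dim sub-2N nuclei in one field, Otsu tracks the
bright mode, drops dim nuclei, and inflates the intensity cut used for the
nuclear masks (biasing integrated DNA content). The default `"auto"`
threshold takes the larger of 10x the background MAD and 2% of the image
maximum — far above shot noise, far below the dimmest nucleus of interest;
`"otsu"` and numeric thresholds remain selectable. Cytoplasmic rings are
grown `ring_width` (default 4) pixels by nearest-nucleus propagation, so
rings never annex a neighbour's pixels. Rendered nuclei are 2-D Gaussians
whose integral is DNA content x gain (default 50 counts/unit over a
200-count background), so a 4N nucleus integrates to exactly twice a 2N
one.

## Endpoints and tests

`percent_of_control()` is the plain ratio treated/control x 100; note it
is survival-direction even though cell-loss assays are often summarized
with it, so the loss-direction quantity has its own unambiguous name,
`cell_loss_percent()`. DNA content
is calibrated by anchoring 2N at the lower major mode of the control
histogram's kernel density (G0/G1 dominates untreated populations) and
classified with bin half-width $\tau = 0.5$N — symmetric "~2N"/"~4N"
windows with no gaps, configurable. Fold changes are plain in-plate mean
ratios. Significance uses the pooled-variance (Student's) two-tailed *t*
at $\alpha = 0.05$ — Student's rather than Welch's form, with Welch behind a
flag; p values are reported per comparison without multiple-testing
correction (a Benjamini–Hochberg step can be applied downstream), and
figures use the four-tier star convention (\*, \*\*, \*\*\*, \*\*\*\* at
0.05, 0.01, 0.001, 0.0001), adopted once rather than inferred per figure.

## Clustering choices

Profile similarity is centered Pearson correlation; the dissimilarity is
$1 - r \in [0, 2]$ (not a metric — documented, not asserted). Linkage is
average (UPGMA) by default, the common default of heat-map viewers, with
complete/single selectable. The default tree cut is height 0.3, i.e.
within-cluster $r \ge 0.7$ — "closely matching" a reference means high
positive correlation. Pairwise correlations use pairwise-complete
features; a pair sharing fewer than 3 features is an error rather than a
silent NaN. Leaf order is recursive tightest-subtree-first (lower merge
height first, leaves counting as height 0, ties on the smallest leaf
index), which is deterministic and keeps heat maps stable across runs.
Newick export places nodes at depth height/2, so leaf-to-leaf path lengths
equal merge heights and the tree round-trips through standard parsers.
Reference clustering can run on either the core or the high-resolution
feature set; both panels work throughout
(`panel = "core"` / `"full"`).

In the orchestrated pipeline the reference library is *screened*, not
injected: reference compounds get their own simulated plates (same
signature set, profiling dose 25 ug/ml) and are scored jointly with the
fractions, mirroring screening practice in which references are
processed by the same method as the unknowns. This matters because screen-max scaling rescales each
feature by the screen's extreme; scoring fractions and references together
keeps their profiles on the same per-feature scale.

## Seeds, sizes and reproducibility

Every stochastic function takes a seed; pipeline stages derive theirs from
the master seed by a polynomial hash of the stage name (`stage_seed()`),
so any stage can be re-run alone. Two runs with the same config and seed
produce byte-identical TSVs (checksummed in `manifest.tsv`). The shipped
test suite uses fixed seeds and the following problem sizes, chosen to
estimate each property comfortably: 20 seeded screens for the score-bound
property; 200 references + 50 fractions over 10 classes at noise sd 0.15
for MoA recovery; 50,000+ cells for phase-fraction recovery (binomial
error ~0.2%); 2,000 replicated t-tests for the type-I rate; 100 random
fields for segmentation-count recovery; 20,000 draws for the
permutation-test cross-check.

## Known limitations

* Screen-max scores are screen-relative; do not compare them across
  independently normalized screens.
* The simulator's class effects are random directions, not measured
  pharmacology; MoA-recovery results quantify the pipeline, not biology.
* Segmentation assumes roughly round, moderately dense nuclei; heavily
  clumped fields will under-segment (the `high` DNA class models the
  consequence, clumps reading as >4N, rather than the cause).
* No plate-position (row/column drift) normalization or B-score/median
  polish; plates are assumed spatially unbiased, as in the simulator.
* No IC50 curve fitting: endpoints are per-dose comparisons against the
  dose-0 group, matching the reported analyses.
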