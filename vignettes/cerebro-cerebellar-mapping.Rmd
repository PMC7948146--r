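---
title: "Individual-specific cerebro-cerebellar network mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-specific cerebro-cerebellar network mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cerebparc)
```

## The problem

The human cerebellum receives its cortical input almost entirely through
crossed cortico-ponto-cerebellar circuits, so each cerebellar hemisphere
mirrors the functional organization of the *contralateral* cerebral
cortex. Resting-state functional connectivity makes this mapping visible
in single subjects: a cerebellar voxel's time course correlates most
strongly with cortical vertices belonging to one functional network, and
assigning each voxel to the modal network among its most-correlated
vertices yields an individual-specific cerebellar parcellation. This
package implements that pipeline end to end and — because the raw
single-subject fMRI such analyses run on is not generally redistributable
— ships a synthetic ground-truth generator so that every stage can be
validated by label recovery.

## The signal model behind the generator

A synthetic subject (`build_scene()`) consists of:

* **Cortex**: two hemispheres of surface vertices, each vertex labelled
  with one of K networks (default K = 10, with conventional names:
  somatomotor, visual, dorsal attention, salience/ventral attention,
  control A/B, default A/B, language, limbic). Network sizes follow a
  moderate linear spread (13% down to 7% of vertices at K = 10), because
  real networks differ in areal extent and a constant size vector would
  make the proportionality analysis degenerate.
* **Cerebellum**: a 2-mm isotropic integer lattice in an MNI-like frame,
  split at x = 0 into hemispheres. Within each hemisphere the in-mask
  voxels are divided into three strata along the anterior–posterior
  axis, each holding a complete representation of the cortical network
  set; the network order of the second stratum is mirrored against the
  first, reproducing the inverted posterior-lobe topography. Somatomotor
  territory is subdivided along the same axis into foot, hand and tongue
  bands with an unlabeled gap between foot and hand (the gap voxels keep
  the somatomotor network label but carry `body_part = "none"`).
* **Lateralization**: one network (default the language network) is
  given a left/right cortical extent ratio of 1.3, and because
  cerebellar extents mirror the contralateral cortex, its cerebellar
  representation is right-biased.

Each run draws one unit-variance latent time course per (network,
cortical hemisphere). A unit's series is

    x = sqrt(snr) * g + e,

with `g` the unit's latent and `e` unit-variance white noise, so the
expected unit–latent correlation is `sqrt(snr / (snr + 1))` (0.707 at
snr = 1) and `snr = Inf` gives noiseless series equal to the latent.
Cerebellar voxels are driven by the latent of their network in the
*opposite* cortical hemisphere — the coupling the winner-take-all stage
is designed to recover. Somatomotor body parts get their own latents,
coupled to the shared somatomotor latent with correlation `sqrt(0.8)`,
so body-part maps are distinct but still cluster as one network.

Latents are white by default. A `latent_band` option restricts them to
a band (e.g. 0.01–0.1 Hz) so that band-pass filtering is
non-destructive; note that band limiting concentrates the signal on
roughly `2 * T * tr * bandwidth` Fourier modes, which inflates chance
correlations between networks — at T = 600 and the 0.01–0.1 Hz band the
effective sample size drops from 600 to about 110. Analyses of recovery
accuracy therefore use the white default.

**What the generator does not emulate**: hemodynamics, motion artifacts,
spatially correlated noise (real data are smoothed), heterogeneity of
connectivity *within* a network, bilateral latent coupling (left and
right instances of a network are independent here), and cortical
geometry (vertices are exchangeable indices, not a sphere). Passing
recovery tests therefore shows the estimators are correct under the
assumed signal structure, not that they are robust to every property of
real fMRI.

## The pipeline

1. **QC** (`run_qc`): a run is excluded iff maximum absolute motion
   exceeds 2 mm (strictly) or temporal SNR is ≤ 130. Both comparisons
   are exactly as stated: motion exactly at 2 mm is kept, tSNR exactly
   at 130 is excluded.
2. **Nuisance regression** (`regress_nuisance`): per-unit least-squares
   projection onto the orthogonal complement of the nuisance design
   (always including an intercept); rank-deficient designs fall back to
   the pseudo-inverse with a warning.
3. **Band-pass** (`bandpass`): frequency-domain masking. Fourier
   coefficients at frequencies inside [low, high] (inclusive) are kept,
   all others zeroed. This is zero-phase by construction and has an
   exactly rectangular amplitude response at the Fourier frequencies.
4. **Seed maps** (`seed_timecourse`, `correlation_map`, `fisher_z`,
   `average_maps`, `contrast_maps`, `threshold_overlay`): Pearson
   correlation of a seed mean time course with every target unit,
   Fisher z = atanh(r) transformed (|r| clamped at 1 − 1e−7 so perfect
   correlations stay finite), averaged across runs, contrasted, or
   thresholded into multi-label overlays (defaults z ≥ 0.1 / 0.2 / 0.1
   for foot / hand / tongue). Zero-variance series yield r = 0 plus a
   mask flag rather than NaN, so downstream voting stays total.
5. **Cortical networks** (`compute_profiles`, `binarize_top_fraction`,
   `cluster_profiles`): each vertex's connectivity profile is its
   correlation to 1175 single-vertex ROIs sampled uniformly across both
   hemispheres; rows are binarized by keeping the top 10%
   (ceil(0.10 × 1175) = 118 entries, ties at the cutoff broken toward
   the lower ROI index) and clustered by spherical k-means on
   L2-normalized rows: best of 20 k-means++-seeded restarts by the
   within-cluster cosine objective, empty clusters re-seeded from the
   least-well-fit points, convergence at objective change < 1e−8 or 300
   iterations. Cluster identities are arbitrary and are matched to a
   reference by exact assignment on the confusion matrix
   (`match_labels`). Clustering is applied per hemisphere because the
   generator's left and right latents are independent; the group prior
   that merges homotopic networks in real analyses is out of scope.
6. **Cerebellar winner-take-all** (`voxel_vertex_connectivity`,
   `parcellate_cerebellum`): run-averaged Fisher-z connectivity of every
   voxel to every vertex; each voxel takes the modal network among its
   k = 400 most-connected labelled vertices. Ties at the k-th rank break
   toward the lower vertex index; vote ties break first toward the
   larger summed z, then the smaller network index. Confidence is the
   winning vote share. Voting uses both hemispheres by default;
   `contralateral_only = TRUE` restricts it.
7. **Evaluation** (`split_half_protocol`, `overlap_percent`,
   `seed_to_cortex_validation`, `network_composition`,
   `proportionality`): odd sessions form the discovery half, even the
   replication half (runs never split across halves). Overlap between
   parcellations is the percentage of identically labelled units among
   units labelled in both. Seed-back validation correlates a cerebellar
   seed back to the cortex and reports an inside-minus-outside z
   contrast plus a size-matched Dice against the target network
   (optionally restricted to the contralateral hemisphere, since
   ipsilateral cortex is independent in the generator). Proportionality
   regresses per-network cerebellar volume fractions on contralateral
   cortical surface fractions, per cerebellar hemisphere.
8. **Flatmap projection** (`project_volume_labels`): each surface vertex
   takes the modal nonzero volumetric label along 21 evenly spaced
   samples of the segment joining its outer- and inner-surface
   coordinates, each sample mapped to the nearest voxel centre (a sample
   exactly midway between centres maps to the higher index; label ties
   break toward the smaller network index). The flatmap is a
   visualization device, not a true unfolding; no template geometry is
   bundled — correspondences come from a 6-column CSV.

## Numerical choices and degenerate regimes

* **Tie rules everywhere are deterministic** (documented above), so
  every stage is bit-reproducible under a fixed seed.
* **The noiseless limit is degenerate in two instructive ways.** With
  `snr = Inf` all units of a network share one latent *exactly*, so
  chance correlations are constant within a network ("blocks"). First,
  whole blocks enter a voxel's top-k wholesale; the true network is
  guaranteed to win only if k is at most twice the smallest
  contralateral network block. The noiseless recovery analysis uses
  3200 vertices per hemisphere so the default k = 400 satisfies this
  bound. Second, within-network vertex–ROI correlations tie at exactly
  1, so binarization at 10% overflows, by rank, into tied chance blocks
  shared between unrelated networks, making their binary profiles
  near-identical; the noiseless clustering analysis binarizes at 3%
  (within one network's own ROI block), which removes the artifact. Any
  nonzero noise removes both degeneracies, and the noisy analyses use
  the 10% default.
* **Vote-count robustness** is assessed with k ∈ {100, 400, 1000} on a
  subject with 4000 vertices per hemisphere, keeping k = 1000 a shallow
  cut (12.5% of vertices) comparable to the regime in which such
  robustness is observed on full-resolution meshes; at 2000 vertices
  per hemisphere k = 1000 would mean voting with a quarter of the
  cortex.
* **Problem sizes.** Validation analyses use 1080 in-mask voxels on a
  14 × 17 × 8 grid and 2000–4000 vertices per hemisphere, with runs of
  418–600 frames at TR = 1 s — large enough that Monte-Carlo error is
  small against every margin tested, small enough to run interactively.
* **Perturbation model** (`perturb_subject`): between-subject
  idiosyncrasy is modelled by repeatedly flipping boundary-adjacent
  labels to a neighbouring network until about `magnitude` of all units
  differ, so label overlap with the source subject is approximately
  1 − magnitude and decreases monotonically in magnitude.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `K` | 10 | number of cortical networks |
| `k` | 400 | voting vertices per voxel (winner-take-all) |
| `keep_fraction` | 0.10 | binarization fraction of connectivity profiles |
| `restarts` | 20 | spherical k-means restarts |
| band | 0.01–0.1 Hz | band-pass edges |
| motion limit | 2 mm | run exclusion threshold (strict >) |
| tSNR floor | 130 | run exclusion threshold (≤ excluded) |
| thresholds | 0.1 / 0.2 / 0.1 | foot / hand / tongue overlay z cutoffs |
| `snr` | 1 | latent-to-noise variance ratio per unit |
| `n_samples` | 21 | samples along each flatmap projection segment |

`load_config()` validates these from YAML/JSON and rejects unknown keys.

## A small worked run

```{r example, eval = FALSE}
scene <- build_scene(vertices_per_hemisphere = 2000, seed = 1)
plan <- acquisition_plan(n_sessions = 4, runs_per_session = 1,
                         frames_per_run = 600, snr = 1)
sessions <- apply_qc(simulate_session_set(scene, plan, seed = 2))
halves <- split_half_protocol(sessions)
cortex <- surface_parcellation(c(scene$cortex_labels_left,
                                 scene$cortex_labels_right), 10)
parc_d <- parcellate_cerebellum(
  voxel_vertex_connectivity(halves$discovery), cortex, k = 400,
  scene = scene)
parc_r <- parcellate_cerebellum(
  voxel_vertex_connectivity(halves$replication), cortex, k = 400,
  scene = scene)
overlap_percent(parc_d, parc_r)$percent_same_label
```

## Known limitations

* The multisession hierarchical Bayesian cortical parcellation used in
  full-scale individual analyses is not implemented; spherical k-means
  on binarized profiles is the clustering stage, and externally supplied
  vertex labels are accepted everywhere a parcellation is consumed.
* No spatial regularization: voxels are assigned independently, so
  salt-and-pepper labels appear at low SNR exactly as they do for real
  winner-take-all parcellations.
* The generator's independence assumptions (between hemispheres,
  between networks, between units' noise) make recovery *easier* than
  on real data with spatially correlated noise; reported accuracies are
  upper bounds in that sense.
* Image registration, surface reconstruction, smoothing and template
  geometry are out of scope; inputs are assumed already in a shared
  grid/index space.
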