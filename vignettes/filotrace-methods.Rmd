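---
title: "Tracing and tracking filopodia with filotrace: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing and tracking filopodia with filotrace: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Axon terminals of developing neurons extend and retract thin membrane
protrusions — filopodia — on a time scale of minutes. Quantifying their
dynamics from two-photon time-lapse stacks requires reconstructing, for every
time step, a skeleton of the terminal: where the terminal center (root) is,
where each filopodium attaches to the terminal body (base), where its distal
end (tip) is, and which filopodium at time $t+1$ is the same biological
object as one at time $t$ (its track). The data are demanding: single
channel, 8-bit, strongly anisotropic voxels (typically
$0.1 \times 0.1 \times 0.5\,\mu m$), modest signal-to-noise, structures one
to two voxels thick, and a slowly drifting terminal.

filotrace implements this reconstruction headlessly. Tip positions of newly
emerging filopodia are the only per-object annotation; everything else —
path geometry, base location, frame-to-frame correspondence, dynamics
statistics — is computed. Corrections are replayable edit commands rather
than interactive clicks, so a full semi-automatic session is a script.

## Tracing: intensity-weighted shortest paths

A filopodium's path from its tip to the terminal center is the minimal-cost
path on the 26-connected voxel lattice under the edge weight

$$ w_{ij} \;=\; \lVert p_i - p_j \rVert \;+\; \frac{2c}{I'_i + I'_j},
   \qquad I'_k = \min(\max(I_k, 1),\, I_{max}), $$

where $p_i$ are voxel centers in world micrometers (so the anisotropic z
spacing enters the distance term directly), $I_k \in [0,255]$ are voxel
intensities, $c$ (default 50) balances path length against brightness, and
$I_{max}$ (default 100) caps the benefit of very bright voxels so that long
detours through a bright body are not rewarded. Two numerical choices are
ours: intensities are clamped below at 1 — the weight would otherwise be
infinite on zero voxels, whereas the clamp keeps them merely maximally
penalized — and cost ties are broken toward the smaller linear voxel index,
which makes every trace deterministic.

Per cropped frame a full single-source Dijkstra tree rooted at the terminal
center is precomputed (`build_tree()`) and stored as a predecessor map; any
tip-to-root trace is then a chain walk (`trace_to_root()`). Pairwise traces
for path corrections run Dijkstra on the fly inside the bounding box of the
two endpoints dilated by `n_margin` voxels (default 10) per axis
(`trace_between()`), large enough for paths that bow outside the tight box.

When a traced path is inserted into the skeleton (`insert_path()`), it is
tested for intersections against the paths already present, on the voxel
grid (same voxel = intersection; sub-voxel geometry is not attempted). A
junction on a filopodium segment makes the new path a branch of that
filopodium — same track, its length added. A junction on the base-to-root
segment starts an independent filopodium. One guard is ours: a junction
closer than `branch_margin` (default 0.3 µm of path) to the host's base is
treated as an independent filopodium sharing the base site. In crowded
terminals the traces of genuinely distinct filopodia converge just outside
the shared base region, and without the margin every such pair would collapse
into one two-tipped filopodium.

## Base detection: the Gaussian-ness change point

Inside a filopodium the transverse intensity profile is approximately
Gaussian; inside the terminal body it is broad and flat. The base is the
change point between the two regimes along the traced path, found by scoring
every path point with the RMSD between sampled transverse intensities and an
ideal fitted Gaussian (`gaussianness()`).

Sampling and fitting involve several choices the problem itself forces:

* **Rays stay near the x-y plane** (spread ±45° around the in-plane path
  normal, both sides, `k_rays` = 8 directions × `n_radii` = 5 radii up to
  `r_max` = 0.35 µm). The axial PSF elongation makes the z profile of even a
  perfect tube several times wider than its x-y profile; rays leaving the
  plane would add a constant anisotropy residual that drowns the tube/body
  contrast.
* **Oblique rays are corrected to effective radius** $r\cos\chi$ (the
  perpendicular distance at which they cross the tube), so a straight
  Gaussian tube is an exact model for every ray.
* **The sampling center is recentered** one mean-shift step onto the local
  intensity ridge before fitting: traced paths run on voxel centers, up to
  half a voxel off the true ridge, and a shifted Gaussian misfits a centered
  model by a large fraction of its amplitude.
* **The offset $b$ is the frame's median intensity** — the dark background —
  not a locally fitted constant. A locally fitted offset lets a flat bright
  body profile be "fitted" perfectly by a constant, erasing the change point
  entirely. With $b$ tied to the true background, $A$ comes from the center
  sample and $\sigma$ from the half-maximum radius of the radial profile
  (robust to truncation of wide profiles at `r_max`), capped at
  $0.6\,r_{max}$: the cap forces the fitted Gaussian of a never-decaying
  profile to decay, which is exactly what makes the body score badly. Since
  $b$ shifts with any global intensity offset and $A$ and the RMSD scale
  with any global gain, detection is invariant to affine intensity
  rescaling.
* **`r_max` = 0.35 µm** spans ≈2.5–3σ of a filopodium's transverse profile
  while staying clear of both the terminal body and neighboring filopodia;
  wider discs graze neighbors in crowded terminals and inflate the in-tube
  RMSD floor. A 10% trimmed RMSD (`trim`) removes the residual effect of a
  single stray ray.

The change-point rule: the smoothed (3-point moving average) RMSD is
thresholded at $\tau = \kappa \times$ the median over the distal quarter of
the path ($\kappa$ = 3). The terminal body extends from the base to the
root, so its suprathreshold region always reaches the root end of the path;
branch crossings produce interior peaks that never do, however wide. The
base therefore bounds the **final** suprathreshold run (dips shorter than
`run_um` = 0.5 µm are bridged), refined to the plateau-onset (80% rise)
point — the base sits on the body surface, where the profile is already
body-like, so the raw $\tau$ crossing on the rising ramp would land
systematically early.

Degenerate inputs: paths shorter than the smoothing window, and paths whose
RMSD never crosses $\tau$ (no body reached), fall back to the root-adjacent
point and are flagged for proofreading.

## Tracking: NCC propagation and retraction rules

Root, base and tip nodes are carried from frame $t$ to $t+1$ by exhaustive
normalized cross-correlation template matching (`match_template()`): the
image box around the node in frame $t$ is compared at every voxel offset
within a search window in frame $t+1$, and the argmax wins if its score
reaches $\gamma$ (0.8 everywhere). NCC is invariant to per-frame gain and
offset changes. Template and search sizes are specified in voxels — root
(15,15,3)/(70,70,7), base (10,10,4)/(50,50,10), tip (10,10,4)/(15,15,4) —
reflecting that roots and bases barely move while tips are highly motile.
Boxes are clipped at image borders (tips often sit near the crop edge), even
sizes center on the floor-half index, and score ties resolve to the smallest
displacement, then lexicographically.

Tip matching alone is not enough: the tube interior is self-similar, so the
NCC argmax sits on a score ridge along the axis and can slide toward the
base over many frames. After matching, the tip is therefore **refined to the
distal end of the local intensity ridge**: walked voxel-by-voxel within a
forward cone (fixed reference direction, so it cannot curve back) while the
next voxel stays above max(θ, 0.9 × the brightest ridge value seen), then
trimmed backward if it stopped on the decaying end cap. The stop threshold
tied to the running ridge maximum also prevents the walk from crossing the
intensity saddle onto a neighboring filopodium.

The retraction rules follow the workflow's semantics: an unmatched tip means
the filopodium has retracted (track ends); an unmatched base keeps its
previous position; a successor whose base-to-tip length falls below `l_min`
(0.5 µm) is removed as retracted. A matched tip farther than the threshold
distance `d` (1.0 µm) from its previous position is rejected as a mismatch
and likewise treated as retraction — the parameter is printed as "the
maximum distance two nodes may be apart to be considered matching", and this
gate is where we apply it. Successors keep their predecessor's track ID;
branching nodes are never propagated but re-emerge from the insertion
intersection test. Every fallback and every retraction decision is recorded
in a structured event log (`get_log()`, JSONL via `write_log()`), so
proofreading can target exactly the uncertain steps. Track IDs are allocated
monotonically and never reused; re-emergence after a true retraction
requires a fresh seed (new track), which `match_filopodium` can later link.

## Preprocessing

The terminal center is clicked once at $t=0$ and propagated by root NCC
matching across all frames. Each axon then gets one fixed-size crop box
anchored to its per-frame root position, so the terminal sits at a constant
voxel position in the cropped series and drift is compensated by
construction. The initial box is estimated by a persistence-filtered
connected-component segmentation: threshold at θ (50), 26-connected
components, then components whose intensity peak rises less than the
persistence p (150) above θ are merged into the brightest component within a
one-voxel dilation — plain connected components cannot separate terminals
that touch, the persistence criterion can. The box is the union over time of
the per-frame component boxes re-anchored to the root, padded by `n_margin`.
Shortest-path trees are precomputed per cropped frame and persisted as
sidecars next to the cropped TIFFs.

## Statistics

From the final 4D skeleton, per track: length per time step (sum of
Euclidean distances along the base-to-tip polyline, branch lengths distal to
the base included), extension/retraction event counts (strictly longer /
strictly shorter than the previous step; exact ties count as neither and are
reported in their own column, preserving
$n_{ext}+n_{ret}+n_{tie} = \text{steps}-1$), mean velocities over event
steps only (µm/min), mean length, lifetime, and the growth angle
$\cos\alpha = \langle v, e_2\rangle / (|v||e_2|)$ with $v$ the root→base
vector projected to the x-y plane and $e_2 = (0,1)$, evaluated at the
track's first time step and reported in degrees in $[0°, 180°]$ (the arccos
is unsigned; a signed bearing is out of scope). Exports are two CSVs
(per-step lengths, per-track summary) with deterministic formatting:
re-exporting the same graph is byte-identical.

## The synthetic data generator

`simulate_series()` renders ground-truthed series that emulate the
acquisition: a uniform-core, Gaussian-edged ellipsoidal terminal body (peak
200), thin curved tubes with Gaussian transverse profiles (peak 180,
σ_xy 0.13 µm), anisotropic axial blur realized as a wider rendering sigma in
z (0.4 µm) rather than a separate convolution pass — ground-truth
centerlines stay exact and the rendered ridge is voxel-exact in x-y, which
the tests rely on — additive Gaussian noise (sd 5) with optional shot noise,
slow whole-terminal drift (default (0.1, −0.05, 0) µm/frame, about one x
voxel per frame), and per-filopodium birth/death schedules with bounded
random-walk length trajectories (step sd 0.15 µm/frame, bounds 0.25–3 µm —
the lower bound deliberately below `l_min` so shrink-below-threshold events
occur). Deterministic trajectories can be programmed via `length_traj` for
rule-exactness tests. Intensity contrast is chosen so the default workflow
parameters (c = 50, I_max = 100, γ = 0.8, θ = 50) work unmodified: that is
the fixture contract for all end-to-end tests.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: photobleaching and focus drift, true two-photon
PSF shape (only its anisotropy), filopodia that genuinely branch over time,
densely crossing filopodia from *other* terminals, and motion blur. Scenes
can still contain effectively unresolvable geometry: two filopodia whose
distal segments converge within a voxel or two are merged by the insertion
logic, exactly as an annotator would need proofreading to separate them —
end-to-end recovery is therefore high but not 100% on crowded random scenes.

## Test and verification sizes

The automated checks run the Dijkstra machinery against a brute-force plain-R
reference on dozens of random lattices up to 8×8×3 (exact equality), recover
100 random integer translations by NCC exactly, localize bases on 20
simulated filopodia (lengths 1–5 µm, σ_xy 0.1–0.2 µm, half with mid-path
branch crossings; median error within 3 x-y voxels), and track a simulated
10-filopodium, 20-frame series under default parameters, requiring ≥90% of
automatically recoverable ground-truth (track, frame) pairs with tip error
≤2 x-y voxels, no spurious tracks lasting ≥3 frames, and removal of exactly
the frames whose true length lies below `l_min`. Recovery is scored up to a
track's first true dip below `l_min`: the rule removes such frames by
design, and re-emergence requires a fresh seed in this workflow, so later
frames are not automatically recoverable. Full pipelines with fixed seeds
are bit-reproducible.

## Known limitations

* Coordinates are voxel-quantized everywhere (tips, bases, polylines); no
  sub-voxel refinement is attempted, so all localization errors have a
  half-voxel floor.
* The intensity cap $I_{max}$ makes all voxels above it equally attractive,
  so traced paths can cut corners within thick bright corridors by up to a
  voxel or two.
* Automatic separation of filopodia whose tubes overlap within the PSF is
  out of reach by construction; the edit operations (`move_tip`,
  `match_filopodium`) are the intended remedy.
* Newly emerging filopodia are never detected automatically; they must be
  seeded, as in the interactive workflow this package scripts.
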