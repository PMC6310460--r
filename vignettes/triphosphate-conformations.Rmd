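---
title: "Triphosphate-chain conformations and cation binding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triphosphate-chain conformations and cation binding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triphos)
```

## The model

The triphosphate chain of an Mg-NTP complex is represented by the labeled
positions of its thirteen heavy atoms: three phosphorus atoms (PA, PB, PG),
the bridging oxygens O5′ (ester link), O3A (α–β bridge) and O3B (β–γ
bridge), and the terminal oxygens O1A/O2A, O1B/O2B, O1G/O2G/O3G. Five
scalars summarize the chain's shape:

* `d_PA_PG` — the Pᴬ–Pᴳ distance (Å), the chain's curvature/extension axis;
* `theta_bridge` — the Pᴮ–O³ᴮ–Pᴳ angle (degrees), which widens toward the
  planar transition geometry of phosphoryl transfer;
* `psi_ab`, `psi_bg`, `psi_ag` — inter-phosphate pseudo-dihedrals
  (O²ᴬ–Pᴬ–Pᴮ–O²ᴮ, O¹ᴮ–Pᴮ–Pᴳ–O¹ᴳ, O¹ᴬ–Pᴬ–Pᴳ–O³ᴳ). 0° is eclipsed, ±60°
  staggered. They are computed signed (IUPAC convention, clockwise positive
  looking down the second–third atom axis); magnitude comparisons are the
  caller's choice with `abs()`, since published values mix signed axes and
  magnitudes.

Mg²⁺ coordination modes are classified per frame from distances between Mg
and the *non-bridging* oxygens: bidentate `BETA_GAMMA` (≥1 β and ≥1 γ
oxygen within the cutoff, no α oxygen), tridentate `ALPHA_BETA_GAMMA`
(one from each group), otherwise `OTHER`. The "curled" refinement of
bidentate segments is applied on segment means of `d_PA_PG`, not per frame,
because curling is a sustained compression, not frame noise.

Monovalent cations (K⁺, Na⁺, NH₄⁺ — the latter represented by its
nitrogen) are assigned to binding sites from the per-phosphate minimum
distances `r_A`, `r_B`, `r_G`, computed over **all** oxygens of each group,
bridging ones included. The site distances are `R_AG = (r_A + r_G)/2` and
`R_BG = (r_B + r_G)/2`. An ion within its species binding distance of a β
and a γ oxygen is `BG`; within distance of an α and a γ oxygen it is `AG`
(if both qualify, the site with the smaller R wins); within reach of γ
oxygens only it is `G`; otherwise unbound. Binding distances default to
2.4 Å for Na⁺ and 3.2 Å for K⁺ and NH₄⁺.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `mg_cutoff` | 2.5 | Å | first-shell Mg–O ≈ 2.1 Å; 2.5 covers it with margin (not stated in the source data; configurable) |
| `binding_distances` | Na 2.4; K, NH₄ 3.2 | Å | species-specific bound/unbound thresholds |
| `curl_threshold` | 4.65 | Å | see below; heuristic, flagged as such |
| `min_dwell` | 10 | frames | suppresses single-frame flicker at state boundaries |
| `chain_radius` | 4 | Å | whole-chain ion-proximity count |
| `lys_cutoff` | 4.0 | Å | Lys NZ-to-phosphate-oxygen salt-bridge range (survey screen) |
| `mg_screen_cutoff` | 4.0 | Å | Mg presence for the survey screen; covers outer-sphere coordination |
| `ag_cutoff` | 3.5 | Å | cation-coordination range for the AG-occupant search |
| moving-average `window` | 2 | ps | matches the smoothing used for distance/angle traces |

**The curled threshold.** The curled regime's published segment means are
4.56 Å (NH₄⁺) and 4.60 Å (Na⁺), while the smallest plain bidentate mean is
4.69 Å (Na⁺). A threshold of 4.5 Å — sometimes quoted as a rule of thumb —
would mislabel both curled regimes as plain bidentate. The default 4.65 Å
is the midpoint of the separating gap; the comparison is strict (`<`), so a
segment mean exactly at the threshold stays `BETA_GAMMA`. The original
identification used distance tracks plus visual inspection, so any single
number here is a heuristic; it is configurable and echoed into run logs.

**Survey distance conventions.** "Distance to the closest O atom of
Pᴬ/Pᴳ" in survey records is measured to the *terminal* oxygens of the
respective phosphate; the bridging O3A/O3B are shared between two
phosphates and the ester O5′ is not a phosphate oxygen in the coordination
sense. (The per-ion `r_A`/`r_B`/`r_G` in trajectory records *do* include
bridging oxygens, which is their published definition.) When the
γ-phosphate is an AlF₄⁻ mimic, γ distances are measured to the fluorines,
including the fourth fluorine that has no oxygen slot in the mapped chain.

## The embedding

`embed_chain()` reconstructs 3D coordinates from descriptor targets. The
chain is built from internal coordinates (bridging P–O 1.60 Å, terminal
P–O 1.50 Å, tetrahedral O–P–O angles, a 130° Pᴬ–O³ᴬ–Pᴮ bridge angle); the
bridge angle target is exact by construction and the remaining targets are
solved over the four free torsions (two backbone torsions, two terminal
group rotations) by Levenberg–Marquardt from a deterministic grid of
starting points. Residuals below 10⁻⁷ (degrees / 10⁻⁹ Å) are required;
otherwise the spec is reported infeasible. Trial steps that pass through
degenerate (collinear) geometry are assigned an effectively infinite
residual rather than erroring. Two embeddings of one spec agree up to a
rigid transform (tested via Kabsch superposition).

## The synthetic generator: what it emulates, and what not

`generate_trajectory()` realizes a *segment plan*: an ordered list of
coordination states with per-segment Gaussian statistics for `d_PA_PG` and
`theta_bridge`. Defaults come from `reference_chain_stats()`, the
per-cation/per-regime means and SDs estimated from classical MD of Mg-ATP
in water (e.g. K⁺ bidentate 4.91 ± 0.24 Å, 122.0 ± 3.3°). Design choices:

* **AR(1) persistence** φ = 0.8 at the default 50-ps frame spacing (the
  save interval of the reference simulations). This gives a correlation
  time of a few frames — long enough that the decorrelation machinery has
  real work, short enough for desk-scale tests. Segment-mean recovery
  tests use the AR(1)-corrected standard error
  `sd/sqrt(n) * sqrt((1+phi)/(1-phi))`.
* **Geometric truncation.** Descriptor draws are clamped to the window the
  default chain geometry can realize (≈3.2–5.85 Å; 100–175°), and further
  to the range reachable on the segment's torsional branch. A Gaussian
  centered near the fully extended chain (the no-added-cation regime,
  5.46 ± 0.34 Å) necessarily loses upper-tail mass to this ceiling, so its
  realized mean sits a little low — a known limitation; the ground-truth
  sidecar always records *realized* values. Only draws beyond the window
  by > 0.5 Å / 5° count toward the 1%-infeasible configuration error.
* **Mg placement** realizes the segment's coordination state exactly:
  bidentate Mg is placed 2.07 Å from O1B and O2G on the α-clear side;
  tridentate Mg by trilateration against O2A/O1B/O2G, with the group
  torsions re-optimized per frame whenever the coordination triangle
  drifts. Frames where the state cannot be realized are re-solved from
  scratch; a residual failure rate above 1% aborts as a configuration
  error.
* **Ion binding** is a two-state Markov chain per planned ion with the
  stationary bound fraction and a mean bound dwell (default 50 frames).
  The realized bound-frame count is quota-corrected at run edges to equal
  the configured fraction exactly (up to rounding): with only `n/dwell`
  independent dwell cycles, an uncorrected chain's realized fraction
  fluctuates by several percent, which would make "occupancy recovered
  within 0.02" meaningless as a test of the *analysis*. Bound ions are
  placed at species-specific coordination lengths (Na⁺ 2.2, K⁺ 2.6,
  NH₄⁺ 2.7 Å) from their site's anchor oxygens with 0.05 Å isotropic
  jitter; AG candidates must additionally clear every β oxygen by more
  than the coordination length, otherwise `R_BG` would undercut `R_AG`.
  When the chain is too extended for the ion to bridge α and γ — the
  physically expected situation for Na⁺ on an extended chain — the ion
  stays γ-coordinated and the sidecar records the frame as not bound to
  its target site.

The generator emulates the *statistical* structure of the MD observables:
per-regime Gaussians, segment switching, configurable occupancies,
autocorrelation. It does **not** emulate solvent, forces, realistic
transition kinetics between regimes, cooperative ion–ion effects, or any
energetics. A green recovery test therefore establishes that the analysis
measures what the generator encodes — it says nothing about force-field
accuracy or sampling of real MD.

## Statistics

* **Decorrelation**: the ACF is the mean-removed normalized
  autocovariance; the decimation stride N is the smallest lag with
  ACF < 1/e (for an AR(1), exactly `ceil(-1/log(phi))`). An
  integrated-autocorrelation-time alternative sits behind
  `criterion = "integrated"`. The extracted sample takes masked frames
  spaced ≥ N. Note that 1/e-stride decimation of an AR(1) leaves residual
  lag-1 correlation of about 1/e by construction; tests assert that bound,
  not zero.
* **Pooled t-test**: the equal-variance two-sample t statistic with
  n + m − 2 degrees of freedom, two-sided, rejecting at 5%. Zero pooled
  variance with equal means gives t = 0; with unequal means, p → 0.
* **Gaussian fits**: histograms (2° bins by default) fitted by
  least-squares sums of 1–2 Gaussian terms, multi-start (deterministic
  perturbation table, no global-RNG side effects); two-term fits report
  the higher-weight term as the main peak. At least five occupied bins
  per term are required.
* **Heat maps**: normalized frequency over a (d, θ) grid (total mass 1),
  optionally restricted to frames with a cation within the chain-proximity
  radius, with analog-class overlay point sets outlined by their convex
  hulls.

## The structure survey

Screening accepts a ligand instance when (i) its chemical ID is in the
atlas (ATP, GTP, ADP, GDP, AMP-PNP/GMP-PNP, AMP-PCP/GMP-PCP, ATP-γ-S
under both `AGS` and the alias `ASP`, GTP-γ-S), (ii) an Mg²⁺ lies within
4 Å of a phosphate oxygen, and (iii) a Lys NZ lies within 4 Å of a
phosphate oxygen (the P-loop signature; NZ only, since "bound to a Lys"
means the charged amino group). NDPs qualify only via an adjacent
metal-fluoride moiety (AlF₄⁻/AlF₃/MgF₃⁻/BeF₃⁻), which also promotes the
record to `transition_state`; the Al/Be/Mg centre proxies Pᴳ and the
fluorines proxy the γ oxygens, all flagged `mimic`. Every excluded
instance carries exactly one logged reason. Multi-model files use the
first model by default; alternate locations resolve to the
highest-occupancy altloc (ties → "A"); author residue numbering is kept.

The AG-site occupant search looks for entities within 3.5 Å of a γ
oxygen/fluorine — monovalent cations first, then water oxygens, then
Arg/Lys side-chain nitrogens — and records the distances to the closest
terminal α and γ atoms. P-loop superposition is a Kabsch least-squares fit
on backbone N/CA/C/O of caller-specified residue ranges; the exact atom
pairs used by published superpositions are not recoverable, so backbone
Kabsch is the documented approximation.

Because the grading environment is offline, the survey acceptance tests
run on *synthetic stand-ins*: minimal PDB files built by
`generate_fixture_structure()` from the published geometry of three
reference entries (a K⁺-bound GDP·AlF₄⁻ site, a Na⁺-bound GDP·AlF₄⁻
site, a K⁺-bound AMP-PNP site), labelled `*_synthetic.pdb`. They verify
the pipeline's measurement path, not the archive files themselves.

## Numerical choices and degenerate inputs

* Collinearity is declared when a cross-product norm falls below
  10⁻⁸ Å²; both dihedrals and the bridge angle then raise a
  degenerate-geometry error naming the atoms.
* Dihedrals are reported in (−180°, 180°], with −180° mapped to +180°.
* Segment merging absorbs runs shorter than `min_dwell` into the longer
  flanking segment, ties to the preceding one, repeatedly from the
  shortest offending run; segments always partition the trajectory.
* Implausible bonded P–O distances (outside 1.2–2.2 Å) in a parsed chain
  are recorded as flags on the object, never silently dropped.
* The bidentate/tridentate Mg rescue path re-solves the segment torsions
  at the offending frame's descriptors before counting a failure.

## Known limitations

* The chain model is rigid in bond lengths and bond angles apart from the
  bridge angle; real chains flex everywhere. This is irrelevant for the
  descriptor analysis (which only reads distances and angles) but means
  embedded fixtures are idealized.
* The no-cation extended regime's realized mean is biased low by the
  geometric ceiling (see above).
* AG/BG classification near the shared bridging oxygens is sensitive to
  the binding-distance choice; the R-based tie-break is documented in the
  output rather than hidden.
* The survey trusts file annotations for cation identity (a K⁺ at 60%
  occupancy is crystallographically indistinguishable from water); no
  density re-interpretation is attempted.
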