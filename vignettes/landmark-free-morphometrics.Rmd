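---
title: "Landmark-free morphometrics of complex bone shapes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-free morphometrics of complex bone shapes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pelvic girdle bones of ricefishes (Adrianichthyidae) — and many other
complex skeletal elements — carry too few repeatable anatomical loci for
classical landmark-based geometric morphometrics. Pelvic-brooding females
develop medial bony tips on the internal wing and basipterygial plate,
wings vary in size, and the lateral process points in different directions
even within one species and sex. `morphfree` implements a landmark-free
toolkit for exactly this setting, in two complementary channels:

* a **2D outline channel**: a binary silhouette is chain-coded, its closed
  outline expanded into elliptic Fourier descriptors (EFDs), normalized by
  the longest-radius rule, and ordinated by covariance PCA;
* a **3D surface channel**: triangle meshes are cleaned and resampled,
  sampled uniformly by area, superimposed to a prototype with a modified
  iterative-closest-point (ICP) algorithm, compared by a Procrustes surface
  metric (PSM), and ordinated from "homologized" closest-point coordinates,
  with per-point deviation fields for heat-map visualisation.

Downstream, the package provides broken-stick axis retention, PERMANOVA
with a strategy-by-sex interaction and a size covariate, range and
convex-hull disparity with bootstrap t-tests, a two-criterion procedure for
choosing the prototype and mesh resolution, and phylogenetic generalized
least squares (PGLS) with a Pagel's-lambda policy.

A synthetic bone-shape generator with fully known ground truth accompanies
the analysis code; every stage is tested against it end to end.

## 2D channel

### Chain coding

`binarize()` thresholds a grayscale silhouette (Otsu's histogram threshold
by default), keeps the largest connected component and fills interior
holes. `trace_chain()` walks the outer boundary with Moore-neighbour
tracing and Jacob's stopping criterion and returns a Freeman 8-direction
chain code (0 = +x, counterclockwise in mathematical coordinates, i.e.
`y = -row`). The chain is validated as closed and is reversed if the traced
polygon comes out clockwise.

### Elliptic Fourier descriptors

For a closed polygon parametrized by cumulative chord length \(t \in [0, T]\),
the coordinate functions are piecewise linear and their Fourier series give
four coefficients per harmonic \(n\):

\[
a_n = \frac{T}{2\pi^2n^2}\sum_p \frac{\Delta x_p}{\Delta t_p}
      \left(\cos\frac{2\pi n t_p}{T} - \cos\frac{2\pi n t_{p-1}}{T}\right),
\]

and analogously \(b_n\) (sine, x), \(c_n, d_n\) (y-series). `A0`/`C0` are the
curve centroid. One harmonic traces an ellipse; 26 harmonics (the package
default, a conventional choice for bone outlines) reconstruct the outlines
of the synthetic cohort to well under 1% of the perimeter.

Two numerical points deserve mention.

* **Parametrization matters.** The EFD of an exact geometric ellipse with
  semi-axes (2, 1) under chord/arc-length parametrization is *not*
  \(a_1 = 2, d_1 = 1\): the first-harmonic coefficients are 1.8284 and
  1.0730 (the arc-length Fourier integrals, which the test suite computes
  independently by quadrature). Only the circle is parametrization-neutral.
* **Projection property.** `efd()` applied to `efd_reconstruct()` output
  returns the truncated coefficients exactly only when the parametrization
  is preserved; `efd()` therefore accepts explicit parameter values
  (`t = attr(reconstruction, "t")`). Re-parametrizing by chord length
  changes coefficients at the \(10^{-3}\) level — a property of the curve,
  not a discretization error.

### Longest-radius normalization

`normalize_longest_radius()` removes translation (curve centroid to the
origin), rotation (centroid-to-farthest-vertex radius onto +x), scale (that
radius to length 1) and the starting point (shifted to the farthest
vertex), then recomputes coefficients in this frame. Ties in the longest
radius (a circle, or an ellipse's two semi-major vertices) are broken
deterministically by the smallest arc-length position and flagged.
Reflections are never applied: left and right bones are biologically chiral
and must remain distinct. Orientation is standardized to counterclockwise
before analysis so coefficient signs are comparable.

### Ordination

`efd_pca()` performs covariance-matrix PCA (not correlation: coefficients
share units and the leading harmonics should dominate, matching the
convention of classical outline-analysis software; a correlation variant
would weight noisy high harmonics up). Coefficients with variance below
1e-12 are dropped. Axis signs are fixed deterministically (largest-|loading|
entry positive) so repeated runs and globally transformed inputs give
identical scores. `efd_wireframes()` inverts the PCA mapping at ±2 SD per
axis — the standard wireframe visualisation of outline shape change.

## 3D channel

### Meshes and sampling

`read_mesh()`/`write_mesh()` handle ascii and binary-little-endian PLY with
fan triangulation of polygonal faces. `clean_and_resample()` merges
duplicate vertices, drops degenerate faces, closes small boundary loops and
adjusts resolution: midpoint subdivision upward, edge collapse downward.
Collapse placement uses the quadric error metric (QEM); midpoint placement
was measured to drift a 5120-face icosphere 1.6% off the unit sphere at
2000 faces, QEM brings this to ~0.4%, inside the package's 1%-of-scale
contract. A link-condition guard keeps the mesh manifold.

`sample_points()` draws area-weighted uniform points (faces proportional to
area, uniform barycentric positions) — the even coverage that
landmark-free superimposition assumes. Sampling is the stochastic element
of the surface channel; seeds make it reproducible.

### Superimposition and the Procrustes surface metric

`initialize_pose()` matches centroids, RMS radii (initial scale) and
principal axes, evaluating all four proper-rotation sign branches and
keeping the best by PSM. Axis signs are canonicalized by projection
skewness so the branch label of a specimen is stable across point samples
— that stability is what makes branch agreement across repeated alignments
a meaningful consistency diagnostic. Mirrored specimens are flagged but
never reflected.

`icp_align()` alternates nearest-neighbour correspondence (kd-tree, exact)
with the SVD least-squares rotation/translation/scale, accepting steps
while the PSM improves; the accepted-step trace is non-increasing by
construction. On noise-free synthetic bones it recovers random rigid+scale
poses to fractions of a degree and PSM below 1e-6 of the bounding box.

The PSM between aligned samples \(A\) (size \(m_A\)) and \(B\) is the
symmetrized RMS nearest-neighbour distance

\[
\mathrm{PSM}(A,B) = \sqrt{\frac{\sum_a d(a,B)^2}{2m_A} +
                          \frac{\sum_b d(b,A)^2}{2m_B}},
\]

zero for identical sets and symmetric by construction. A one-directional
variant (`symmetric = FALSE`) supports sensitivity checks.

### Generalized alignment

`gpsa()` superimposes every specimen to the prototype, homologizes each
prototype point to the specimen's closest point, replaces the prototype by
the mean of homologized points, and repeats until the mean PSM stops
improving (again an accepted-step loop). Ordination is covariance PCA of
the homologized coordinate rows — coordinates, not signed distances, an
interpretation choice; coordinates retain directional information and make
the per-axis loading fields (`gpsa_pc_field()`) directly interpretable on
the surface. Per-point deviation is the across-specimen RMS distance from
the prototype, exported as a per-vertex `quality` channel in PLY
(`deviation_heat_export()`) for heat maps.

Specimens are flagged as misaligned when their final PSM exceeds the
cohort median + 3 IQR *and* 1.5 times the median (the relative guard keeps
tight identical-shape cohorts from being flagged on sampling noise), or
when their initialization branch disagrees with the modal branch in two or
more alignment repeats.

Scale removal (`allow_scale`) defaults to on, the Procrustes convention;
centroid sizes are recorded separately so size can be analysed either way
— relevant because pelvic brooders also have absolutely larger pelvic
bones.

### What a prototype can and cannot show

Structure absent from the prototype is invisible to prototype-to-specimen
correspondences: if the reference bone lacks medial tips, specimens' tips
protrude into space where no prototype point anchors them, and the
deviation field stays flat. The package's localization test therefore uses
a tip-bearing prototype — and this is exactly why a reference specimen
should cover the morphological variation of the dataset. The same
mechanism means a pathological prototype *compresses* measured variation
rather than inflating it, which motivates the two-criterion selection
procedure below.

## Prototype and resolution selection

`consistency_screen()` runs the generalized alignment `repeats` times per
prototype-by-face-count combination with fresh sampling seeds and counts
misaligned specimens (union across repeats, PSM rule plus branch
instability). Criterion 1 is strictly prior: only combos with the fewest
misalignments survive. `disparity_screen()` then z-scores each surviving
combo's retained scores per axis (within combo — the transform that makes
different mesh resolutions comparable), assembles one matrix, bootstraps
the sum-of-ranges and convex-hull indices per combo, and chooses the combo
with the smallest median hull, breaking ties by the largest median range
and then by `(face_count, prototype_id)` order, flagged. The premise:
larger morphospaces with less interspecimen structure indicate alignment
noise. Medians within 1% (the order of the bootstrap error of a median)
are treated as tied, so resampling noise never decides the choice. The
full metric table and pairwise Bonferroni t-statistics are always
returned, so a user can overrule the lexicographic rule.

Candidates listed in `prototype_only` are used purely as starting
references (excluded from the specimen set and the ordination) — useful
for evaluating an external or deliberately bad reference without letting
its own score row shape the morphospace. In the package's outlier
experiment, the hull comparison between two same-resolution combos is run
on raw retained scores: per-combo z-scoring exists for cross-resolution
comparability and would cancel precisely the alignment-noise scale the
comparison is meant to detect.

## Downstream statistics

* **Broken stick** (`broken_stick()`): retain leading axes while the
  observed eigenvalue proportion exceeds
  \(b_k = \frac1p\sum_{i=k}^p 1/i\), stopping at the first failure. Equal
  eigenvalues retain zero axes; pipeline callers fall back to one axis
  with a note.
* **PERMANOVA** (`permanova()`): sequential (Type-I) sums of squares on
  Euclidean distances of retained scores with free row permutation
  (the `vegan::adonis2` convention), \(p = (1 + \#\{F^* \ge F\})/(1 + n_\mathrm{perm})\),
  so 9999 permutations give an attainable floor of \(10^{-4}\). The term
  order is fixed as written — strategy, sex, strategy:sex,
  standard_length — by encoding interactions as explicit combined factors
  (the sequential SS of the interaction is the rank increment over the
  preceding terms either way; R's canonical expansion would silently move
  it after the covariate). A species-first ordering is available by
  passing a different formula; species and strategy are partially
  confounded, so both orderings are worth reporting.
* **Disparity** (`disparity_indices()`): sum of per-axis ranges and the
  convex-hull boundary measure, bootstrapped by resampling specimens
  within group. Hulls are exact in up to three dimensions (segment,
  perimeter, surface area — an own incremental hull; no external geometry
  library is required); configurations spanning more than three axes are
  measured on their three highest-variance directions and flagged.
  Degenerate configurations fall back to their affine span; groups smaller
  than \(d+1\) points skip the hull with a flag. `disparity_ttests()`
  compares bootstrap distributions pairwise by Welch t-statistics with
  Bonferroni correction over pairs.
* **PGLS** (`pgls_fit()`, `pgls_scan()`): GLS with covariance
  \(V(\lambda)\) — the Brownian shared-path matrix with off-diagonals
  scaled by \(\lambda\) — with \(\hat\lambda\) by maximum likelihood on
  \([0,1]\) and a likelihood-ratio test against \(\lambda = 1\) using the
  50:50 \(\chi^2_0{:}\chi^2_1\) boundary mixture. If the test is not
  significant the model is refit at \(\lambda = 1\) and that conservative
  fit is reported. Polytomies enter the covariance as true
  multifurcations. A star phylogeny or \(\lambda = 0\) reduces exactly to
  OLS; fixed-\(\lambda\) fits agree with `nlme::gls` + `ape::corPagel` to
  1e-8 in the test suite. With only eight species the boundary LRT is
  markedly anticonservative (about 24% false rejections under Brownian
  motion in simulation) — an asymptotics problem, not an implementation
  one (the same code is calibrated at 2% on 50 tips). This is a concrete
  argument for the conservative set-\(\lambda\)-to-1 policy at small
  species counts; the package's calibration test runs at 50 tips where the
  test's nominal level is meaningful.
* The **dimorphism response** for PGLS is the male minus female
  species-mean score per axis, not a quotient: PC scores cross zero, so a
  ratio is numerically unstable. The quotient remains available
  (`ratio = TRUE`).

## The synthetic generator

`base_outline()` builds a star-shaped polygon from smooth von-Mises-style
radial bumps: an elongated anterior arm, a posterior plate, unequal
internal and external wings (fixed chirality — reflections are never
generated), and a narrow lateral process. `shape_spec()` parametrizes
deformations: medial-tip amplitude (three narrow bumps in the medial
sector), internal-wing scaling, the lateral-process angle drawn from
\(N(0, \sigma^2)\) per individual, smooth low-order radial noise, overall
scale, and 3D vertex jitter. `make_mesh()` extrudes the deformed outline
into a thin, closed, bilaterally asymmetric plate whose rim tapers sharply,
with the angular resolution floored at 128 steps so narrow features (tips,
process) survive even at low face counts; the face count lands within 10%
of target (usually exactly) via QEM collapse. Poses are random rigid
transforms plus scale, recorded exactly in the ground truth
(`unpose()` inverts them to 1e-9).

`make_cohort()` mirrors the study design: eight species (five transfer
brooding, three pelvic brooding), five females and five males each except
one species with 3+4 — 77 specimens; specimen size follows the
standard-length covariate; species-level offsets to the tip amplitude
evolve by Brownian motion with a Pagel-\(\lambda\) transform on the
(polytomous, ultrametric) default tree.

Default effect sizes are package choices, selected once for
clear-but-not-trivial recovery at five specimens per species and sex:
tips 0.30 of the base radius in pelvic-brooding females only, internal
wing ×1.30 (females) and ×1.15 (males) in pelvic brooders, lateral-process
SD 8°, radial noise SD 0.012, vertex jitter 0.002 of the bounding box,
Brownian rate 0.02. With them, the strategy-by-sex PERMANOVA interaction
is recovered at \(\alpha = 0.01\) in well over 90% of replicate cohorts.

What the generator does *not* emulate: real bone metrics (it reproduces
the qualitative anatomical contrasts, not measured shapes), fin rays
(non-rigid structures excluded from shape comparison), left/right
asymmetry beyond the fixed chirality, segmentation artifacts, or
scanner noise. Passing tests therefore demonstrate that the pipeline
recovers planted effects of realistic structure — not that any particular
biological dataset would yield particular values.

## Problem sizes and numerical choices

The package's own analyses run at desk scale: outlines with 192–256
vertices, meshes of 700–2000 faces, 400–5000 surface points per specimen,
999–9999 permutations, 200–5000 bootstrap replicates. The acceptance
script uses the full 77-specimen cohort at 2000 faces and 3000 surface
points — a sampling density chosen so correspondence noise (which scales
as one over the square root of the point count) sits below the planted
effect sizes, mirroring the role of the study's much denser meshes. The
3D morphospace statistics use the leading six axes, the study's reduced
set; the broken-stick rule applied to a noise-dominated surface spectrum
is deliberately stricter and would retain fewer.

Other numerical choices: ICP stops when the PSM improves by less than
`tol` (1e-7) times the prototype bounding-box diagonal, with a 200
iteration cap; the generalized alignment outer loop stops on the same
scaled tolerance; PCA drops coefficients with variance below 1e-12;
longest-radius ties are declared within a 1e-9 relative band; hull
visibility uses a 1e-10-of-extent tolerance; the lambda optimizer compares
the interior optimum with both boundaries.

## Known limitations

* The exact conventions of the original outline software (its
  longest-radius reflection handling, coefficient standardization before
  PCA) are not published; the package's contract is stated above and the
  covariance/correlation switch is explicit.
* Prototype-to-specimen correspondences lose structure absent from the
  prototype (see above); deviation fields should be read with the
  prototype's coverage in mind.
* The convex-hull boundary measure is exact only up to three dimensions;
  higher-dimensional configurations are projected (flagged) rather than
  measured in full dimension.
* PGLS inference at eight species rests on the conservative
  \(\lambda = 1\) policy, not on the nominal level of the boundary LRT.
* 2D analyses assume silhouettes are taken along a consistent axis; the
  manual orientation step of a real μ-CT workflow is out of scope, and
  `binarize()`/`trace_chain()` start from the image as given.
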