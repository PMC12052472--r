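---
title: "Quantifying eggshell ornamentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying eggshell ornamentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

External eggshell ornamentation — the sculpted nodes, ridges and chains
that decorate many dinosaur and some avian eggs — has traditionally been
described with a handful of qualitative categories. Those categories
overlap, are inconsistently applied, and cannot support statistical
comparison within or between taxa. `eggscore` quantifies ornamentation
from 3D surface meshes with three complementary per-section metrics and
provides the statistical pipeline needed to compare eggs, clutches and
taxa.

The unit of analysis is a *standardized section*: a nominally 10 mm
diameter patch of shell surface, aligned so its best-fit plane is
horizontal and decimated to exactly 5000 triangular faces. Fixing the
sampling area and the face budget makes the metrics comparable across
specimens, scanners and mesh densities. Each egg contributes many
sections (30 or more), binned into five equal-length zones along the
egg's long axis with zone 1 at the acute pole.

## The three metrics

**Complexity — Dirichlet normal energy (DNE).** For a face with vertices
$v_1, v_2, v_3$ and unit vertex normals $n_1, n_2, n_3$, let
$u = v_2 - v_1$, $w = v_3 - v_1$, $\nu = n_2 - n_1$, $\omega = n_3 - n_1$
and

$$G = \begin{pmatrix} u \cdot u & u \cdot w \\ u \cdot w & w \cdot w \end{pmatrix},
\qquad
H = \begin{pmatrix} \nu \cdot \nu & \nu \cdot \omega \\ \nu \cdot \omega & \omega \cdot \omega \end{pmatrix}.$$

The energy density is $e = \operatorname{tr}(G^{-1} H)$ and the mesh DNE
is $\sum_f e_f A_f$ over retained faces. A plane has $e = 0$; a sphere
has $e = 2/r^2$, so its total is $8\pi$ at any radius — DNE is invariant
under uniform scaling, which is why it can compare eggs of different
sizes. Vertex normals are computed by angle-weighted averaging of
incident face normals. Faces on the open rim of a section carry
unreliable normals, so boundary faces are discarded before summation
(the default "vertex" rule drops any face touching a boundary vertex;
an "edge" rule and "none" are available). Finally the top 0.1% of
$e \cdot A$ contributions are trimmed, which suppresses the occasional
near-degenerate face without touching signal; the fraction is a
setting and all three choices are echoed in the SCORE CSV header.

**Relief — mean slope.** Each face's slope is its angle from the
horizontal, $\arccos |n_z|$ in degrees. The undirected normal folds rare
overhanging faces into $[0^\circ, 90^\circ]$. The relief metric is the
unweighted mean over retained faces; an area-weighted mean is available
as a setting (the unweighted mean matches per-mesh averaging at face
granularity; the area-weighted variant is what analytic integrals such
as the hemisphere's 1-radian mean slope test against).

**Directionality — orientation.** Each face normal is projected into
the horizontal plane; its azimuth (counterclockwise from +X, in the
frame where the egg's long axis is +Y) assigns the face's area to one of
eight 45° bins. Bins 1, 4, 5 and 8 collect normals within 45° of the ±X
directions — the flank normals of ridges running pole-to-pole — and the
complementary bins 2, 3, 6, 7 collect area facing around the short
axis. With $SA_\parallel$ and $SA_\perp$ the two area totals,

$$\Omega = 100 \, \frac{SA_\parallel - SA_\perp}{SA_\parallel + SA_\perp}
 \in [-100, +100].$$

$\Omega = +100$ means every non-flat face belongs to pole-to-pole
structure; $-100$ the opposite; $0$ no preferred direction. The mapping
from the area ratio to the bounded scale is the unique smooth, bounded,
sign-symmetric choice (equivalently $100(R-1)/(R+1)$ for the ratio
$R$); it is isolated in one function so an alternative transform can be
swapped in without touching the binning. Faces whose normal projection
is shorter than `vertical_tolerance` (default $10^{-9}$) are flat-on and
excluded; bin areas plus the excluded area always reconstruct the total
retained area. A perfectly flat section has no definable direction and
raises an error rather than returning an arbitrary value.

## Standardization choices

*Alignment* replaces an interactive mesh-editor step with a
least-squares plane fit: the smallest principal direction of the vertex
covariance becomes +Z (sign chosen so the mean face normal points up),
the centroid moves to the origin, and the in-plane projection of a
user-supplied long-axis hint maps to +Y. The hint must be supplied as
metadata because the orientation metric is meaningless without knowing
where the egg's poles are. The hint is interpreted in the mesh's current
coordinates, so re-aligning an already-aligned mesh with the default
hint `c(0, 1, 0)` is a no-op — the idempotence the tests assert.

*Decimation* is quadric edge collapse with area-weighted face-plane
quadrics. Boundary edges contribute perpendicular constraint planes
(weighted by squared edge length times `boundary_weight`, default 100)
so the rim of an open section stays put; collapses that would pinch the
rim, break the link condition or flip a face normal are rejected.
Interior collapses remove two faces and boundary collapses one, which
lets the loop land exactly on the 5000-face budget. On a closed mesh
every collapse removes two faces, so a target of the wrong parity stops
one face high with a warning — irrelevant for sections, which always
have a rim. Default quality controls (boundary weight, optimal-position
solve with midpoint/endpoint fallback) are recorded here because
interactive tools do not report theirs.

*Section extraction* keeps faces whose centroids lie within the section
radius measured in the tangent (X-Y) plane. For low-relief shell this
differs negligibly from a true cylinder Boolean and remains robust on
open meshes.

## Statistics

Metric distributions per egg are screened with Shapiro–Wilk (reported,
never used to switch methods silently); on real eggs they are
right-skewed and non-normal, which motivates the whole non-parametric
chain. Outliers are removed per egg and per metric with an asymmetric
IQR rule: below $Q_1 - 1.5\,\mathrm{IQR}$ or above $Q_3 + 3\,\mathrm{IQR}$
(the larger upper multiplier tolerates the right tail). Quartiles use
linear interpolation between order statistics (`quantile` type 7); the
convention is stated because it changes which points are outliers.
Filtering is a single pass, applied per egg; a pooled per-taxon mode is
deliberately not the default.

Distributions are compared with the exact two-sample Kolmogorov–Smirnov
test, which needs no distributional assumptions and accepts unequal
sample sizes. The p-value is computed by counting label arrangements
with a lattice dynamic program conditioned on the observed pooled
multiset, so ties are handled exactly and all comparisons are integer
arithmetic. Above the feasibility guard ($nm > 10\,000$) the asymptotic
Kolmogorov tail is used and flagged. The exact computation is verified
in the test suite against full enumeration for all $n, m \le 8$ and
against `stats::psmirnov` at larger sizes.

One consequence of exactness worth knowing: the null distribution of
$D$ is discrete, so the test's realized size at a nominal $\alpha$ can
sit well below $\alpha$. At $n = m = 10$ the attainable p-values nearest
0.05 are 0.0524 ($D \ge 0.6$) and 0.0123 ($D \ge 0.7$); strict rejection
at $p < 0.05$ therefore occurs with null probability 0.0123, not
$\approx 0.05$. This conservatism is a property of any correct exact KS
test at small equal sample sizes, not an implementation artifact.

The three per-metric p-values for a pair of eggs are not independent
(complexity and relief in particular are strongly rank-correlated), so
they are combined with the harmonic mean $k / \sum_i p_i^{-1}$ rather
than an independence-assuming method. The harmonic mean always lies
between the smallest and largest input. As a test statistic the raw
harmonic mean is mildly anti-conservative; a calibrated option returns
the exact null tail $P(\mathrm{HMP}_k \le x)$ for $k$ independent
uniform p-values, computed by recursive quadrature of the $k$-fold
Pareto(1) convolution for $k \le 5$ and by a large fixed-seed Monte
Carlo sample for larger $k$. The raw mean compared against
$\alpha = 0.05$ remains the default significance call.

Between-group effect sizes are reported as bootstrap percentile 95%
confidence intervals of the mean difference (1000 iterations, seed
mandatory). Metric inter-relationships use Spearman's rank correlation
(Pearson correlation of mid-ranks).

## The synthetic-surface generator

Real scan data cannot ship with the package, so every metric and the
whole pipeline are exercised on generated sections. A section is a
height field over a 10 mm disc: radially symmetric Gaussian nodes
(default 30 per section, 0.2 mm high, $\sigma = 0.4$ mm), Gaussian-profile
ridges extruded along a chosen azimuth (default 5 ridges, 0.2 mm high,
$\sigma = 0.5$ mm, running along the long axis), and a band-limited
smooth noise field (16 random cosines below 1.2 cycles/mm, 0.02 mm SD).
Those amplitudes sit in the few-tenths-of-a-millimetre range of real
ornamented eggshell; smooth noise rather than white noise keeps DNE
finite as resolution grows. The default grid (12 vertices/mm, about
22 600 faces) leaves realistic headroom above the 5000-face standard.

Two generator choices exist purely to make construction-based tests
sharp. First, node centres are drawn from a fixed-size seeded pool, so
raising `node_count` adds nodes to the same arrangement instead of
reshuffling everything — density ladders are nested and complexity
rises monotonically along them. Second, a height field has no
overhangs, which keeps slope in the undirected regime by construction.

A synthetic egg is 5 zones × `sections_per_zone` sections (30 by
default), each section's zone assigned from its relative position along
the long axis via the half-open five-interval rule (upper endpoint
closed into zone 5 — a boundary convention that had to be fixed
somewhere). Per-zone parameter overrides support ornamentation
gradients, e.g. fading from the acute to the blunt pole.

What the generator does *not* emulate: pores, taphonomic cracks,
scanner noise correlated with surface color, curvature of the whole egg
within a section, and eggshell microstructure. Passing tests on
synthetic clutches therefore demonstrate the correctness and power of
the measurement and comparison machinery under controlled conditions,
not field performance on damaged or poorly scanned material.

## Numerical choices and degenerate inputs

* Zero-area faces carry zero normals and are skipped by every metric
  (counted, never fatal); a face with singular first fundamental form is
  skipped from DNE with a reason recorded per face.
* Azimuth binning uses half-open bins $[45(k-1), 45k)$ and the bin
  index is computed after rotating azimuths into the long-axis frame,
  so a non-default long-axis azimuth permutes nothing.
* Rotations by multiples of 90° (used when testing orientation
  antisymmetry) are applied with `cospi`/`sinpi`, which are exact at
  those arguments.
* PLY output prints doubles with `%.17g`, making write/read round trips
  bit-exact; all CSV writers use binary-mode connections and fixed
  formats so identical runs produce identical bytes on any platform.
* STL vertex welding is by exact coordinate equality by default; a
  tolerance merge is available but off, to keep round trips stable.

## Problem sizes in the test suite

The suite builds everything it tests at run time: icospheres and
analytic surfaces for the metric oracles (5120-face sphere for the
$8\pi$ check, 1% tolerance on the hemisphere slope integral),
grid-resolution-6 sections (about 5600 faces) for pipeline tests, full
enumeration KS oracles up to $n = m = 8$, 2000 null simulations for the
KS size check, and 500 simulated pairs for bootstrap CI coverage. These
sizes were chosen to exercise every code path at meaningful precision
while keeping the default test run fast.

## Known limitations

* The orientation metric degrades on very low-relief surfaces, where
  most face normals approach vertical and binning becomes noise-driven;
  on a perfectly flat section it is undefined by design.
* Exact KS p-values are conservative at small sample sizes (see above);
  pairwise comparisons between eggs with few retained sections inherit
  that conservatism.
* Decimation of a closed mesh cannot always hit an exact odd/even face
  target (parity), and extremely degenerate meshes may run out of
  admissible collapses before the target; both cases warn.
* The per-bin area accounting includes every non-vertical face; no
  minimum patch size is imposed before summation.
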