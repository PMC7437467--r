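---
title: "Methods: collective-coordinate permeability, hydrophobic mismatch, and filter geometry"
author: "aqpflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collective-coordinate permeability, hydrophobic mismatch, and filter geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `aqpflux`, the assumptions
behind them, the choices we made where the methodology is genuinely open, and
what validation on the synthetic generators does and does not demonstrate
about real membrane trajectories.

## The collective coordinate and its diffusion constant

Water transport through a single-file channel is condensed into one
dimensionless coordinate per monomer channel,

$$\mathrm{d}n \;=\; \sum_{i \in s(t)} \frac{\mathrm{d}z_i}{L},$$

where $s(t)$ is the set of waters inside the channel at time $t$,
$\mathrm{d}z_i$ their axial displacements over one frame interval (Å,
minimum-image unwrapped), and $L$ the channel length (Å). The normalization
makes one full permeation change $n(t)$ by exactly $\pm 1$; `aqpflux` tests
this identity to $10^{-9}$ on a scripted traversal. Under equilibrium
conditions $n(t)$ behaves as a 1D random walk, and the Einstein relation
$\langle n^2(t) \rangle = 2 D_n t$ yields the channel's intrinsic transport
rate $D_n$ (1/ps). Osmotic permeabilities follow as
$p_{u,\mathrm{mon}} = v_w D_n$ and $p_{u,\mathrm{tet}} = 4\,p_{u,\mathrm{mon}}$
(cm³/s; the conversion factor Å³/ps → cm³/s is $10^{-12}$).

**Channel region.** The channel is a finite cylinder: lateral minimum-image
distance to the axis ≤ `radius` and $z_\min \le z \le z_\max$. The boundary
is a modelling choice, not an observable; defaults are `radius = 4` Å
(an aquaporin monomer pore plus first hydration shell) with $L$ supplied per
system (the aquaporin Z pore spans roughly 20–28 Å). All four monomer
channels of a tetramer are specified independently.

**Entry/exit bookkeeping.** An interval's displacement is accumulated only
for waters inside the channel at *both* endpoint frames
($s(t_k) \cap s(t_{k+1})$). This symmetric rule avoids double-counting the
displacement of entering/exiting waters, makes the increments antisymmetric
under time reversal, and preserves the ±1-per-permeation identity in the
channel interior; a water that dips into one channel end and retreats
contributes exactly zero net.

**Windowing and the fit.** The per-channel series is divided into
consecutive, non-overlapping windows of `window_ps = 200` ps, each re-based
to start at zero, and the windows of all channels are pooled into one MSD
(a 50-ns tetramer run gives 250 segments per channel, 1000 pooled).
Non-overlapping windows keep segments approximately independent, which a
sliding window would not. $D_n$ is half the ordinary-least-squares slope of
the MSD over the full lag range with a *free intercept*; the free intercept
absorbs short-lag artifacts so that a nonzero dynamical offset does not bias
the slope. The slope standard error (halved) is reported alongside.

**$v_w$.** The average volume of a water molecule defaults to 29.9 Å³
(bulk molar volume 18.07 cm³/mol divided by Avogadro's number) and is
configurable.

## Hydrophobic mismatch

Bilayer hydrophobic thickness is proxied by the phosphorus-to-phosphorus
distance $d_{P-P}$: leaflets are assigned by sign of $z$ relative to the
mean-$z$ midplane of all selected P atoms, and the thickness of a region is
the difference of leaflet mean $z$ within it. The leaflet-mean definition
(rather than nearest-neighbor P pairing) stays well defined when the region
holds only a handful of lipids, the regime of the adjacent shell. A genuine
monolayer cannot be detected from the mean-$z$ midplane alone; the reader
errs only when atoms sit exactly on the midplane.

The **adjacent shell** is the set of P atoms whose minimum lateral
(xy, minimum-image) distance to any protein atom is at most `cutoff = 5` Å.
"Contiguous to the protein" has no unique definition; 5 Å captures the first
lipid shell at typical areas per lipid (~64 Å²) and the cutoff is always
reported in the output.

$\Delta d_{P-P,\mathrm{adj}} = d_{P-P,\mathrm{origin}} - d_{P-P,\mathrm{deform}}$,
positive when the annulus is compressed. $d_\mathrm{origin}$ comes by
default from a separate protein-free reference trajectory, measured with the
same schedule; a constant reference value may be supplied instead (covering
the alternative of using distal lipids of the same system, whose thickness
the user can measure with `thickness()` directly).

**Schedule.** The representative value averages five evaluations spaced
1 ns apart over the initial 5 ns; each evaluation is a block average of the
frames within half a spacing of the evaluation time. Block averages (rather
than single instantaneous frames) were chosen because the per-frame shell
estimate at realistic noise has Å-scale scatter that the block average
suppresses without extending the schedule; both the number of points and the
spacing are configurable.

## Selectivity-filter central area

Per frame, the filter's four residues each contribute the atom closest to
the mean of the four residue centroids (all-atom centroids by default —
supplying Cα-only atom sets switches the center to Cα-based; exact ties go
to the lowest atom index, making the pick deterministic). The atom is
re-picked every frame by default, matching a per-frame reading of
"closest"; `repick = FALSE` freezes the frame-1 atoms for stability
comparisons. The four points are projected onto the plane perpendicular to
the channel axis (+z by default, the membrane normal), ordered by polar
angle about their projected centroid, and the area evaluated by the shoelace
formula. Angular ordering guarantees a simple quadrilateral whatever the
input order; collinear projections legitimately give area 0. Histograms use
0.5-Å² bins anchored at 0, with masses normalized to 1.

## System-level prediction

$\rho_\mathrm{prot}$ is the protein count over the time-averaged $L_x L_y$
cross-section (Å² → cm²: $10^{-16}$). The membrane permeability trend is
$p_f \propto \rho_\mathrm{prot} / \Delta d_{P-P,\mathrm{adj}}$; the
proportionality is meaningful only for compressive mismatch, so
$\Delta d \le 0$ yields a flagged, unranked entry rather than a negative
trend. The correlation of $p_{u,\mathrm{tet}}$ with $1/\Delta d$ uses the
sample Pearson $r$ with the two-sided p-value from
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ degrees of freedom. At small $n$
the $t$ null is an approximation to the exact permutation null; the package
provides a Monte-Carlo permutation p (`pearson_permutation_p`) as a
cross-check, and the test suite bounds their disagreement by the
permutation's Monte-Carlo error plus a ~20% small-sample allowance.

## The synthetic generators: what they emulate, and what they do not

**Channel waters** (`gen_channel_water`): $N_w$ independent waters per
channel doing 1D Brownian motion along $z$ with diffusion constant $D_w$,
laterally jittered inside the pore radius. Independence gives the exact
closed form $D_n = N_w D_w / L^2$ (variance additivity of the collective
increments), which is what the pipeline is validated against. The defaults
($N_w = 8$, $D_w = 0.2$ Å²/ps, $L = 20$ Å, dt = 1 ps, 4 channels) are an
aquaporin-like occupancy and pore length with single-file-scale mobility.

*Boundary mode.* The default is **periodic**: $z$ wraps with period $L$ and
the box height equals $L$, so the minimum-image unwrapping recovers every
true increment and the closed form holds at all lag times — this emulates
the physical situation in which waters exchange with the reservoirs and the
channel occupancy stays statistically constant while $n(t)$ diffuses freely.
A **reflective** mode is provided for qualitative use, but note its MSD
saturates: a water confined to $[0, L]$ has limiting displacement variance
$L^2/6$, and whenever $2 D_w \tau$ approaches that bound within the fit
window (already true at $\tau = 200$ ps for the default parameters, where
$2 D_w \tau = 80$ Å² vs. $L^2/6 \approx 66.7$ Å²), the fitted slope falls
well below $2 D_n$. That is a property of reflected Brownian motion, not an
estimator defect, which is why reflective mode carries no closed-form
recovery target.

The generator does *not* emulate single-file exclusion, water–channel
interactions, correlated motion between waters, or entry/exit kinetics; a
single-file lattice variant was considered and left out because it admits no
closed form to validate against. Passing recovery tests therefore
demonstrates the correctness of the bookkeeping, windowing, MSD and fitting
machinery — not that $D_n$ of a real aquaporin equals any particular value.

**Bilayer** (`gen_bilayer`): P atoms on square lattices at $z = \pm d_0/2$
(spacing 8 Å, i.e. 64 Å² per lipid; $d_0 = 38$ Å, typical of POPC), a ring
of dummy protein atoms at radius 20 Å (an aquaporin tetramer footprint),
both leaflets displaced inward by $\tfrac{A}{2} e^{-u^2/(2\sigma^2)}$ with
$u$ the distance to the protein surface, lattice sites under the protein
removed, and i.i.d. Gaussian z-noise per frame ($\sigma_z = 0.5$ Å, the
scale of P-atom thermal roughness). The planted truth for any cutoff is the
shell average of the analytic thinning profile, computed independently of
the pipeline from the per-atom distances. Not emulated: lipid diffusion and
exchange between shells, undulations, leaflet asymmetry, protein tilt and
drift. The 50-frame/5-ns default matches the analysis schedule.

**Filter** (`gen_filter`): four two-atom residues (inner marker + outer
decoy, so the closest-atom rule is exercised every frame) on squares of
area $A_1 = 5$ or $A_2 = 9$ Å² — the two occupied states of a flexible
filter — switching as a symmetric two-state Markov chain
(`p_switch = 0.02`/frame) with 0.1-Å vertex jitter. Truth is the planted
state sequence. Not emulated: continuous conformational paths between
states or correlated vertex motion.

All generators are bit-reproducible given (config, seed), and every
generated system round-trips through the package's PDB (1 mÅ precision) and
DCD (float32) writers and readers.

## Numerical and I/O choices

- Coordinates are held as R doubles in memory; DCD's native float32
  truncation is applied exactly once on write, and all accumulated
  statistics (MSD sums, leaflet means) are double precision.
- Only orthorhombic boxes are supported; triclinic DCD unit cells are
  rejected with an explicit error, and both the 90°-angle and 0-cosine cell
  conventions are accepted on read.
- Frame times are never trusted from DCD headers (writer fields are
  unreliable across simulation engines); `dt_frame` is a required user
  input.
- `segment_series` requires the window to be an integer multiple of
  `dt_frame` and discards the trailing remainder; consecutive windows share
  their boundary frame so the covered intervals are disjoint.
- Degenerate inputs have defined behavior: empty selections are legal for
  `select_atoms` but rejected by every downstream operation that needs
  atoms; an empty adjacent shell warns and the subsequent thickness errors;
  a negative fitted slope reports zero permeability with a warning while
  retaining the raw `D_n`; collinear filter projections give area 0.
- Atom indices are 0-based internally (file order), residue numbers 1-based
  as in PDB.

## Problem sizes used in validation

The test suite and the acceptance script validate at: 200,000 frames × 4
channels × 8 waters for the permeability chain (3,996 pooled 200-ps
segments, recovering $D_n$ to a few percent at fixed seed); 512 lipids + 50
frames for the mismatch chain (recovering the planted shell average to
< 0.2 Å); 2,000 frames for the filter chain. These sizes were chosen so the
statistical error of each estimator is several times smaller than its
validation tolerance.

## Known limitations

- The permeability estimate assumes the channel axis is +z and fixed;
  tilted or drifting pores need the anchored-center option and are otherwise
  out of scope, as are curved axes and HOLE-style pore profiling.
- $\Delta d$ from a single reference trajectory inherits that reference's
  finite-sampling error; the reported per-point values let the user judge
  it.
- The `p_f` trend is proportional, not absolute: no attempt is made to
  convert $\rho/\Delta d$ into cm³/s for the whole membrane.
- PDB chain identifiers are single characters and residue numbers wrap at
  four digits on write, as the fixed-column format dictates.
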