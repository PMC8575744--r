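---
title: "Methods: xanthophyll orientation and interaction dynamics in bilayer trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: xanthophyll orientation and interaction dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific setting

Lutein and zeaxanthin carry a hydroxyl on each terminal ionone ring, which
anchors the rings in the polar interfaces of a phosphatidylcholine bilayer.
The molecules are therefore positionally restricted: the default orientation
is transmembrane (vertical, V), with one ring at each interface, while a
horizontal (H) placement — both rings below one interface — is possible but
less stable. `xanmem` quantifies, from coordinate trajectories, the
observables that discriminate the two orientations and the interactions
stabilising them: ring-torsion state populations and hopping, ring-COM
trajectories against the interface reference planes, polar-contact counts,
interaction-lifetime decay curves, long-axis rotation, and RDFs. This
vignette records the models, parameter choices and numerical decisions; the
README shows worked examples.

## Units, containers, conventions

All coordinates are Å and all times ps internally; GRO input (nm) is
converted on read. This single-unit contract avoids silent factor-10 errors
between the two supported formats. Boxes are orthorhombic only — triclinic
input is rejected with a clear error, which keeps the minimum-image code
simple (`d - box * round(d/box)` is exact for orthorhombic cells).
Dihedrals use the IUPAC sign convention (cis = 0°, trans = 180°, result in
(−180, 180]); the test suite pins the convention against an independently
coded projection formula. Note the symmetries: reversing the atom order
*preserves* a torsion angle, while a mirror reflection negates it.

Centres of mass are mass-weighted and computed without unwrapping molecules
across the periodic boundary. The synthetic generator never splits a
molecule across the box; for real input, `checkMoleculesWhole()` warns when
a residue's extent exceeds half the box. A whole-cell unwrapping subsystem
is deliberately out of scope. Whether ring COMs should be mass-weighted or
geometric is not settled usage; mass-weighting is the package's choice, and
because all ring pseudo-atoms are carbons the two coincide for the
synthetic systems, so nothing downstream is sensitive to it there.

Atom selections go through an `AtomClassMap` (role → residue/atom-name
lists, YAML-overridable) rather than hard-coded names, because file
dialects differ in atom naming while the chemistry is fixed. The shipped
default covers POPC (phosphate Op = O13/O14, esterified Oe = O11/O12,
glycerol Og = O21/O31, carbonyl Oc = O22/O32, choline N + 3 CH~3~), LUT/ZEA
(primed atoms suffixed `P`, e.g. `C3P` for C3′) and 3-site water.

## Torsion dynamics

The hopping rotations are two-state processes: the ε-ring torsion
(C5′–C6′–C7′–C8′) has minima near 130° and −50°, the β-ring torsion
(C5–C6–C7–C8) near +30° and −30°. State windows must be chosen because the
literature reports minima, not widths; the defaults are centre ± 40° for
the ε states (covering the observed 100–150° oscillation band) and
centre ± 25° for the β states (the maximum keeping the windows disjoint).
Frames outside every window are `unassigned`. A transition is recorded when
the label changes between assigned states and the new state persists at
least `minDwell` ps; the default is 0 ps, because sub-200 ps excursions are
physically meaningful events for these torsions, and the window/dwell pair
is exposed as configuration rather than guessed as fixed truth. All angle
arithmetic is circular (differences wrapped into (−180, 180]), so the
assignment is invariant under ±360° shifts. Histograms default to 5° bins
and report densities, not counts, so trajectories of different length
compare directly.

## Orientation classification

Per frame and leaflet, the interface is referenced by the mean z of the P
atoms and of the glycerol O atoms (leaflets assigned by sign of z relative
to the instantaneous bilayer centre, the midpoint of the leaflet P means;
no lipid flip-flop handling, as none occurs on these scales). The
interfacial slab is the interval between the glycerol-O and P reference
planes padded by `tol` (default 2 Å): the natural reading of drawing those
two reference lines, since no numeric thresholds accompany them in common
use. A molecule is V when its two ring COMs lie in opposite slabs, H when
both lie in the same slab, and `transit` otherwise — an explicit third
label instead of forcing a binary call on ambiguous frames.

Frame-level flicker is suppressed by a running-majority window (`smoothing`,
default 1 ns) and H/V runs shorter than the window are demoted to transit.
A reorientation event is a maximal transit run bounded by two different
stable labels; its end time (start of the new stable label) is the reported
reorientation time, which is meaningful at the tens-of-ns resolution such
events are quoted at. The generator's flip schedule defines truth as the
time the new orientation is established, so detection accuracy is bounded
by `smoothing + frame stride`, and the tests assert exactly that bound.

For horizontal molecules the polyene plane stands perpendicular to the
bilayer surface with the methyl (MET) substituents of the two chain halves
pointing in opposite directions along the normal; `planeOrientation()`
labels a molecule `beta_up` when the β-half MET mean z is on the water side
of the ε-half's (mirrored in the lower leaflet), i.e. the β-ring hydroxyl
points to water. Long-axis rotation θ uses the MET–C13 bond sampled every
100 ps: for V molecules the angle of its x–y projection against the x axis,
for H molecules the angle against the z axis within the vertical plane
containing the long axis; unwrapping takes nearest-image angular steps
(valid while per-sample steps stay below 180°, which the 100 ps stride
guarantees for realistic rotation rates). Hydrophobic width is
operationalised as the distance between the leaflet mean carbonyl-oxygen
planes (an acyl-carbon variant is available), since the scalar is
conventionally quoted without its estimator.

## Polar contacts

Hydrogen bonds are geometric: donor–acceptor oxygen distance ≤ 3.25 Å and
donor–H···acceptor angle ≥ 135°. These cutoffs are the package's defaults
in the lineage of standard membrane-simulation practice — the interactions
themselves are named in the literature without printed criteria — and every
summary carries the criteria used. Hydroxyls are evaluated both as donors
(to PC oxygens and water) and as acceptors (from water). Water bridges
require one water simultaneously H-bonded to the hydroxyl and to a PC
oxygen in the same frame, counted once per (OH, PC-oxygen) pair regardless
of how many waters bridge it — pair-level counting prevents double counts.
Charge pairs use a 4.0 Å cutoff from the hydroxyl oxygen to the nearest
choline N/CH~3~ carbon, per lipid.

`buildEventMatrix()` runs a detector over all frames (default every 1 ps)
and stores a boolean pair × frame "firm bonding" matrix; episodes
(`bondEpisodes()`) are maximal runs of consecutive bonded frames — the
dot-raster content of per-partner bonding-history panels.
`summarizeContacts()` averages per-frame per-OH counts over time and OH
groups, split by ring (ε/β) and, when orientation labels are supplied, by
H/V with transit frames excluded; the `All` row sums the PC-oxygen classes
before averaging, so it equals the sum of its parts exactly.

## Lifetime decay and multi-exponential fitting

The decay statistic allows returns: at each origin t₀ the bonded pairs are
marked, and C(τ) counts how many of them are bonded again (not necessarily
continuously) at t₀+τ, averaged over origins. Origins are evenly spaced
(default every 1 ns, from an equilibration offset that defaults to 0 for
synthetic data); the statistic is stationary-invariant to the origin set,
which the tests check. For a stationary two-state telegraph pair with rates
(k~on~, k~off~), C(τ)/C(0) = p + (1−p)·e^(−(k_on+k_off)τ) with
p = k~on~/(k~on~+k~off~) — the closed form used as the statistic's oracle.

Fitting uses the model C(τ) = C₀ Σᵢ (Aᵢ/100) e^(−τ/Tᵢ) with no constant
term (a plateau is absorbed by a large slowest T). Positivity of amplitudes
and time constants is enforced by optimising in log space; unweighted least
squares on the linear scale (no weighting convention is established for
these curves); multi-start Levenberg–Marquardt with log-spaced initial time
constants over [sample spacing, lag] and jittered restarts (default 16),
best SSE kept. Components are reported sorted by ascending T with A as
percentages of the fitted total, so ΣA = 100 by construction and label
switching across restarts cannot occur. Standard errors come from the
Gauss–Newton covariance at the optimum (delta method for the normalised
amplitudes). Fits are deterministic given their seed argument. Two time
constants within 5 % of each other flag the fit `degenerate` rather than
being silently reported. Residual diagnostics report max |r|/C(0), the
residual sd, and a Wald–Wolfowitz runs test on residual signs — a
structured-residual detector that flags under-fitting (e.g. a
three-exponential signal fitted with two components).

Whether published decay analyses fit raw counts or curves normalised to
C(0) = 1 is ambiguous; `xanmem` fits unnormalised counts with a free C₀
and reports percentages, which reproduces the ΣA = 100 structure of
published tables either way.

## RDFs

Minimum-image pair histograms, normalised per frame by the ideal-gas
expectation from the instantaneous box volume and target count (self-pairs
excluded for self-RDFs), averaged over frames. Default bin 0.1 Å; `rMax`
must not exceed half the smallest box length. The normalisation uses the
full box volume, not a slab-corrected density: in a bilayer the water and
lipid densities are far from uniform, so absolute g(r) plateaus will not be
1 for interface species. The curves are intended for comparative peak
analysis (presence, position, height), and a slab-aware normalisation is a
documented non-goal. Water RDFs default to water oxygens only
(configurable), the common convention.

## The synthetic generator: what it emulates, and what it does not

`syntheticTruth()`/`generateBilayer()` produce trajectories whose
*statistical structure* matches prescribed truth, not physically realistic
configurations. Defaults mirror the studied system class: 188 POPC, 6
xanthophylls, ~8,500 waters in an 80 Å cube; P planes at ±20 Å, glycerol-O
at ±15 Å, carbonyl-O at ±15.15 Å (hydrophobic width 30.3 Å by
construction); rigid rods of C3–C3′ length 28.3 Å; 1 ps frame spacing.
Lipids are leaflet-anchored pseudo-molecules jittered about their planes
(σ = 0.5 Å per frame, a realistic interface roughness scale that leaves
plane means recoverable); xanthophylls sit at lattice-cell centres, maximally
distant from lipid sites, so no accidental contacts arise. Ring torsions
are realised by moving the off-axis C5/C5′ atoms to angles from two-state
Markov chains with Gaussian angular noise (σ = 8°); ε rates default to 0
(no hopping, the bilayer situation) and β rates to 0.002/0.004 ps⁻¹ (fast
switching, 2:1 occupancy of +30°, matching the qualitative 1:2 population
asymmetry). Orientation flips interpolate tilt and depth linearly over a
transit window (default 20 ns) ending at the scheduled flip time. Long-axis
rotation is rigid spin: Brownian (D = 0.1 deg²/ps by default, enough for a
full turn within a µs-scale trajectory), frozen, or a deterministic ramp.
Per-hydroxyl water bonding is a telegraph process (defaults k~on~ = 0.007,
k~off~ = 0.003 ps⁻¹, stationary on-probability 0.7) realised geometrically:
a dedicated water sits at collinear 2.8 Å O···O geometry while "on" and is
displaced to 6 Å while "off" — unambiguous under any reasonable H-bond
criteria. Everything is bitwise deterministic given the seed.

Not emulated: realistic densities and packing, lipid conformational
dynamics, PC-partner bonding geometry (PC-directed telegraph processes are
exercised through the geometry-free `generateEventMatrix()` fast path
instead), correlated interface undulations, and any force-field energetics.
Consequently, passing tests demonstrate that the *analysis stages recover
known statistical truth* — detector correctness, estimator calibration,
event-timing accuracy — not that the generator reproduces real membranes.
Conclusions about real systems still require real trajectories.

## Problem sizes and determinism in the shipped checks

The test suite and the acceptance script run at desk scale by design:
decay-curve fits use 5,001-point lag grids (30,001 where a ~9.5 ns
component needs a longer window); telegraph checks use 10³ pairs over a few
ns; oracle-equivalence sweeps use 500 random frames of a small mixed
system; orientation-truth sweeps use 16-lipid slabs with coarse (≥ 2 ps)
sampling, including a 700 ns span at 500 ps stride for the scheduled
500 ns flip; the structural-scalar checks use the default plane geometry
with reduced counts. Statistical assertions use 3σ bands derived from the
relevant effective sample sizes (telegraph chains decorrelate over
1/(k~on~+k~off~)); exact assertions (detector equivalence, telegraph
recovery, rod length) are equality checks. All randomness is seeded;
reruns are reproducible, and the pipeline writes a manifest with every
parameter so a run can be reproduced from its outputs.

## Known limitations

- Orthorhombic boxes only; no XTC/TRR/DCD binary readers (text GRO/PDB
  keep the package dependency-light and the fixtures inspectable).
- No molecule unwrapping: split molecules in real input are detected and
  warned about, not repaired.
- RDF normalisation is not slab-corrected (see above).
- The contact detectors assume PC oxygens have no hydrogens (true for PC)
  and water is a rigid 3-site model; other water layouts enter via the
  class map.
- Interaction lifetimes are reported as fitted components without a
  physical interpretation layer for what each component represents.
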