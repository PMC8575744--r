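# xanmem

Analysis of xanthophyll (lutein, zeaxanthin) behaviour in phosphatidylcholine
bilayer trajectories.

Lutein and zeaxanthin are polar carotenoids whose hydroxylated ionone rings
anchor in the two interfaces of a lipid bilayer, giving the molecules a
predominantly transmembrane ("vertical") orientation; lutein can also sit
"horizontally" below one interface. Which orientation a molecule adopts, and
how stable it is, is governed by a web of weak polar interactions — hydrogen
bonds of the ring hydroxyls with water and with lipid phosphate/carbonyl
oxygens, water bridges, and choline charge pairs — together with the
conformational freedom of the ring torsions. `xanmem` provides the trajectory
analyses needed to quantify all of this for membrane simulations of
POPC/xanthophyll systems, plus a synthetic bilayer generator with known
ground truth so every stage can be validated without running molecular
dynamics.

## What it computes

- **Trajectory I/O and geometry** — multi-frame GRO and PDB readers/writers
  (orthorhombic boxes, Å/ps internally), minimum-image distances, dihedrals
  (IUPAC convention, cis = 0°), mass-weighted centres of mass, and a
  role-based atom-class map (`Op`, `Oc`, `Og`, choline, ring atoms, ...)
  configurable via YAML.
- **Torsion dynamics** — per-molecule time series of the ring torsions
  (ε ring: C5′–C6′–C7′–C8′, two states near 130° and −50°; β ring:
  C5–C6–C7–C8, states near ±30°), circular population histograms, two-state
  assignment with a dwell filter, and hopping-rotation (transition) counting.
- **Orientation** — ring-COM z trajectories against the per-leaflet P and
  glycerol-O reference planes, horizontal/vertical/transit classification
  with majority smoothing, reorientation-event timing, β-up/β-down
  polyene-plane assignment for horizontal molecules, long-axis rotation θ
  (MET–C13 bond, 100 ps stride), apparent C3–C3′ length, hydrophobic width,
  and xanthophyll–xanthophyll aggregation checks.
- **Polar contacts** — geometric H-bond, water-bridge and charge-pair
  detectors (explicit criteria, defaults: donor–acceptor ≤ 3.25 Å,
  D–H···A ≥ 135°; charge pair ≤ 4.0 Å), firm-bonding event matrices sampled
  every ps, Table-style per-OH/per-ps contact summaries grouped by ring and
  orientation, and per-partner bonding-episode (duration-panel) extraction.
- **Interaction lifetimes** — the returns-allowed decay curve

  C(τ) = ⟨ Σ_pairs 1[bonded at t₀] · 1[bonded at t₀+τ] ⟩ over origins t₀,

  in which broken-and-reformed bonds are counted again, and its constrained
  decomposition C(τ) ≈ C₀ Σᵢ (Aᵢ/100) e^(−τ/Tᵢ) with Aᵢ ≥ 0 (Σ Aᵢ = 100)
  and Tᵢ > 0, fitted by multi-start Levenberg–Marquardt in log-parameter
  space, with standard errors and residual/runs-test diagnostics.
- **RDFs** — minimum-image radial distribution functions between arbitrary
  selections, ideal-gas normalised from the instantaneous box volume.
- **Synthetic bilayer generator** — leaflet-anchored POPC pseudo-lipids
  (P/glycerol-O/carbonyl-O planes at ±20 / ±15 / ±15.15 Å), rigid 28.3 Å
  xanthophyll rods with prescribed torsion Markov chains, scheduled
  horizontal→vertical flips, long-axis rotation (diffusive, frozen or
  ramped), and per-hydroxyl water-bonding telegraph processes realised in
  geometry — fully deterministic per seed, with the realised truth returned
  for comparison.

## Worked example

Round-trip the published four-exponential decomposition of the
zeaxanthin-OH···water H-bond decay (A in %, T in ps):

```r
library(xanmem)
ref <- referenceDecayParameters()
p <- ref[ref$system == "ZEA", ]
cur <- generateDecayCurve(A = c(p$A1, p$A2, p$A3, p$A4),
                          T = c(p$T1, p$T2, p$T3, p$T4),
                          C0 = 100, lag = 5000)
fit <- fitMultiExp(cur, n = 4)
fit
#> MultiExpFit: 4 components, C0 = 100
#>   component     A        seA       T        seT
#> 1         1 22.46 1.5780e-15    2.17 3.7419e-16
#> 2         2 30.52 1.0080e-15   72.10 3.8828e-15
#> 3         3 31.51 8.6657e-16  488.70 2.0002e-14
#> 4         4 15.51 6.3150e-16 2981.30 9.5582e-14
fitResiduals(fit)$maxAbsRelative
#> 1.42e-16
```

The fit recovers the generating constants to machine precision: a fast
~2 ps component (~22 %), two dominant intermediate components at ~72 ps and
~490 ps (~31 % each), and a slow ~3 ns tail (~16 %).

Analyse a synthetic bilayer with known truth end to end:

```r
truth <- syntheticTruth(nPopc = 16, nXan = 2, nWater = 30, seed = 1)
gen <- generateBilayer(truth, duration = 2000)   # 2 ns, 1 ps frames
cm <- defaultClassMap()
gen$trajectory
#> Trajectory: 424 atoms, 2001 frames
#>   residues: POPC LUT SOL
#>   time span: 0 .. 2000 ps
#>   box (frame 1): 80.00 x 80.00 x 80.00 A

bem <- buildEventMatrix(gen$trajectory, cm, "hbond", partners = "water")
bem
#> BondEventMatrix (hbond): 4 pairs x 2001 frames; fill 0.818

ml <- molecularLength(gen$trajectory, cm)
sprintf("C3-C3': %.2f +/- %.2f A", ml$mean, ml$sd)
#> "C3-C3': 28.30 +/- 0.00 A"
hw <- hydrophobicWidth(gen$trajectory, cm)
sprintf("hydrophobic width: %.2f +/- %.2f A", hw$mean, hw$sd)
#> "hydrophobic width: 30.29 +/- 0.18 A"
```

The detected bonding rows equal the generator's telegraph truth bitwise
(`gen$truth$bondingOn`); the rigid-rod length and the carbonyl-plane
separation reproduce the construction values 28.3 Å and 30.3 Å.

The configuration-driven pipeline (`runPipeline()`) chains the stages and
writes CSV tables, a decay-fit table, and a JSON manifest recording every
criterion used; `scripts/run_pipeline.R` is a thin command-line wrapper.

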