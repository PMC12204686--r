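# spiroscan

Quantitative structural analysis of AdhE spirosomes and, more generally, of
oligomeric enzyme assemblies with internal substrate channels.

Bifunctional aldehyde–alcohol dehydrogenase (AdhE) converts acetyl-CoA to
ethanol through a cytotoxic acetaldehyde intermediate and polymerises into
helical filaments ("spirosomes") that occur in *extended* and *compact*
conformations. Whether the extended filament seals an internal channel that
shuttles acetaldehyde between the aldehyde-dehydrogenase (ALDH) and
alcohol-dehydrogenase (ADH) active sites is a structural question that turns
into a set of quantitative ones: how much surface do the oligomer interfaces
bury, how many inter-protomer salt bridges and hydrogen bonds stabilise each
conformation, is the channel enclosed or solvent-exposed, what lines it, how
conserved is it, and how long does a channelled ligand reside before escaping
to solvent. `spiroscan` implements each of those analyses as a tested,
reusable module, plus a synthetic-data module so the whole pipeline is
verifiable without downloading a single structure.

## What it computes

* **SASA / buried surface area** — Shrake–Rupley solvent-accessible surface
  area with a deterministic generalized-spiral point set;
  `BSA = SASA(A) + SASA(B) − SASA(A∪B)` between chain groups (total, both
  sides summed; the per-side value is `BSA/2`).
* **Contact networks** — inter-protomer salt bridges (basic side-chain N of
  Arg/Lys/His vs carboxylate O of Asp/Glu, d ≤ 4.0 Å) and heavy-atom hydrogen
  bonds (N/O/S donors, N/O acceptors, d ≤ 3.5 Å, optional antecedent-angle
  filter), with unique residue-pair counts.
* **Grid-probe tunnel finder** — lowest-cost path on a 3-D occupancy grid
  where a node is open if a probe sphere clashes with no atom; edge cost
  `step × 1/(clearance − r_probe + ε)` biases the path through wide lumens.
  Reports the centerline, per-point clearance radii, widest point,
  channel-lining residues, and a solvent-enclosure profile
  (enclosed/exposed per centerline point, by flood fill from bulk).
* **Composition & conservation** — amino-acid composition; channel-vs-protein
  log2-fold enrichment `log2[((c_a+α)/(C+20α)) / ((p_a+α)/(P+20α))]` with a
  Jeffreys pseudocount α = 0.5; MSA column conservation relative to a
  reference row; Needleman–Wunsch global identity (BLOSUM62, terminal gaps
  excluded from the denominator); `GxGxxG`-style motif scanning;
  cross-species homology of mapped residue sets.
* **Trajectory channeling metrics** — residence time before a sustained
  excursion (> 10 Å for ≥ 5 frames, both configurable) with explicit
  censoring ("the true residence time is at least the trajectory length"),
  ensemble means flagged as lower bounds under censoring, hydrogen-bond
  occupancy, and adherence of the ligand path to a tunnel centerline.
* **Ultrastructure statistics** — an implemented Mann–Whitney U test (exact
  p by full enumeration for n₁+n₂ ≤ 12, otherwise normal approximation with
  tie and continuity corrections), per-group length summaries, and
  conformation proportions with Wilson 95% intervals.
* **Synthetic data** — generators for every fixture class (toy multimers
  with designed contacts, sealed/windowed channel phantoms, escape-programmed
  ligand trajectories, conservation-programmed MSAs, two-group length
  samples), each returning machine-readable ground truth verified internally
  by brute force.

Rigid-body superposition uses the Kabsch SVD construction with
sequence-matched Cα pairing for cross-structure comparisons.

## Worked example

```r
library(spiroscan)

## a sealed channel phantom with known geometry
phantom <- makeChannelPhantom(seed = 1, tubeLength = 16, radius = 3)
tun <- findTunnel(phantom$structure, phantom$anchors$start, phantom$anchors$end)
tun
#> Tunnel: 28 points, length 16.20 A, bottleneck 2.51 A, widest 2.64 A (grid 0.60 A)
mean(enclosureProfile(phantom$structure, tun) == "enclosed")
#> [1] 1
```

The tunnel finder recovers the programmed 16 Å tube (clearance ≈ the 3 Å
lumen radius minus grid discretisation) and classifies every centerline
point as enclosed — the behaviour expected of an extended-conformation
channel; carving a side window into the phantom flips the window-adjacent
points to "exposed".

```r
## ligand residence before escape, on a programmed ensemble
ens <- makeSyntheticTrajectories(seed = 1, n = 3, dt = 0.1,
                                 hazardPerFrame = 0.01, nFrames = 2000)
res <- lapply(ens$trajectories, residenceTime)
meanResidence(res)
#> $mean [1] 10.8   $sd [1] 10.45897   $n [1] 3   $nCensored [1] 0   $lowerBound [1] FALSE
pathAdherence(ens$trajectories[[1]], ens$tunnel)
#> [1] 1
```

Three replicates under a 1% per-frame escape hazard escape at frames 103, 6
and 215 (10.3, 0.6, 21.5 ns); the ligand tracks the tube centerline in every
pre-escape frame. Had any replicate never escaped, the ensemble mean would
be flagged `lowerBound = TRUE`.

```r
## two-group length statistics at the published scale (n = 1250/group)
lens <- makeLengthSamples(seed = 1)   # native 80 nm vs exogenous 60 nm, sd 25
tab <- lengthTable(lens$data)
mannWhitneyU(tab$length_nm[tab$group == "native"],
             tab$length_nm[tab$group == "exogenous"])
#> Mann-Whitney U = 1.082e+06 (n1=1250, n2=1250), two-sided p = 2.284e-62 [normal_approx]
lengthSummary(lens$data)
#>       group    n     mean       sd   median fracAbove
#> 1 exogenous 1250 61.58641 24.97721 60.68818    0.0736
#> 2    native 1250 79.59459 25.71784 78.92065    0.2120
```

A 20 nm mean shift at this sample size is overwhelmingly significant, and
the long-filament tail (`fracAbove`, the fraction longer than 100 nm)
differs threefold between the groups.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates one fixture of every synthetic class under the given seed, runs
the full combined pipeline against the installed package — interface BSA,
contact networks, tunnel + enclosure + lining, MSA conservation, trajectory
residence metrics, and length statistics — and writes the acceptance JSON to
`--out`.

## Command line

A thin wrapper over the same functions lives at
`inst/scripts/spiroscan.R` (`report`, `synth`, `lengths` subcommands); the
configuration is a flat `key = value` file read by `readRunConfig()`, and
`runReport()` writes one JSON/TSV per stage plus a manifest, with no
timestamps so reruns are byte-identical.
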