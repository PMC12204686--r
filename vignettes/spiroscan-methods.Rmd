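---
title: "spiroscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spiroscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models behind each module, the tunable parameters
and why their defaults are what they are, what the synthetic-data generators
do and do not emulate, and the places where the design was genuinely open
and a choice had to be made.

## The scientific setting

AdhE spirosomes are helical filaments of a bifunctional aldehyde–alcohol
dehydrogenase. Two protomer interfaces build the filament: a large
domain-swapped dimer interface (one protomer's ALDH domain packed between
the ADH and ALDH domains of its partner) and a smaller "tetramer" interface
between ADH domains of adjacent dimers. The filament occurs in extended and
compact conformations, and the mechanistic question is whether the extended
form seals an internal channel connecting the ALDH and ADH active sites so
that the cytotoxic acetaldehyde intermediate is channelled rather than
released. Each module below quantifies one facet of that question.

## Structure model

Structures are parsed from PDB or mmCIF into a flat atom table (one row per
atom) carrying author residue numbering — the numbering used whenever
specific residues (catalytic cysteine, the ADH-site triad, the glycine
motif) are cited, so no renumbering is ever applied. Assumptions and
conventions:

* **Heavy atoms only.** Deposited cryo-EM models carry no hydrogens, so all
  geometric criteria (hydrogen bonds, salt bridges, clearances) are defined
  on heavy atoms. Hydrogens present in an input are parsed but no criterion
  depends on them.
* **Alternate locations** collapse to the highest-occupancy conformer at
  read time, so every downstream count is deterministic.
* **Waters** are retained but always flagged hetero; SASA and contact
  analyses operate on polymer atoms only unless asked otherwise.
* **van der Waals radii** come from one Bondi-style table applied uniformly
  (C 1.70, N 1.55, O 1.52, S 1.80 Å, with standard extensions for metals),
  declared in `R/utils.R`. An unknown element is a hard error naming the
  atom rather than a silent default.

Superposition uses the Kabsch SVD construction with the determinant
correction, so reflections are never returned; degenerate (collinear) point
sets are rejected since the rotation about the line would be arbitrary.
Cross-structure comparisons pair Cα atoms through a global
Needleman–Wunsch alignment (BLOSUM62, gap open 10 / extend 0.5) with gapped
positions excluded.

## SASA and buried surface area

Shrake–Rupley with a deterministic generalized-spiral point set
(Saff–Kuijlaars construction) rather than random sampling: the quadrature is
then bit-reproducible at fixed `nPoints`. Defaults: probe 1.4 Å (water),
960 points per atom. On fixtures, doubling the point count moves totals by
well under 0.5%, which is the resolution claimed for any reported area.

**Convention.** "Buried surface area" is reported as the *total*
`SASA(A) + SASA(B) − SASA(A∪B)` — both sides summed, no division by two —
with the per-side value (`total/2`) also emitted in reports. The literature
quotes interface sizes in both conventions without always saying which;
the total is chosen here because it is the quantity the defining formula
produces, and emitting both removes the ambiguity for downstream readers.

Which chains constitute "the dimer" versus "the tetramer" interface of a
deposited filament is not derivable from the coordinate file alone, so the
interface functions require explicit chain groups rather than guessing.

## Contact networks

No publication states the exact geometric criteria behind reported salt
bridge and hydrogen-bond counts, so the detectors use the field's common
defaults and expose every threshold:

* **Salt bridge**: any side-chain nitrogen of Arg/Lys/His within 4.0 Å of
  any side-chain carboxylate oxygen of Asp/Glu across the interface, one
  contact per residue pair at the minimum atom distance. Histidine's
  protonation is unknown in heavy-atom models; it is included as a donor by
  default and switchable (`includeHis = FALSE`).
* **Hydrogen bond**: heavy-atom donor–acceptor distance ≤ 3.5 Å over a
  residue-chemistry table (N/O/S donors bearing a proton, N/O acceptors;
  main-chain and side-chain atoms both eligible). An optional antecedent
  filter requires the angle antecedent–donor–acceptor ≥ 90°, rejecting
  acceptors that sit behind the donor's covalent neighbour; it is off by
  default because the published counts appear to be distance-based.

Unique-pair counts are over unordered (chain, residue) pairs pooled across
the listed interfaces, which is how a single per-structure number is quoted
when comparing the extended and compact conformations. Counts under these
defaults are reproducible orderings, not bit-exact reproductions of any one
program's output.

## Grid-probe tunnel finder

A deliberately simple stand-in for Voronoi-based tunnel software, labelled
`grid-probe` in every report. On a regular grid (default spacing 0.6 Å,
chosen as ≈ 1/5 of a typical channel radius; nodes ordered x fastest, then
y, then z, which fixes all tie-breaks):

* a node is **open** when a probe sphere centred there clashes with no atom
  (clash = centre distance < atom vdW radius + probe);
* **clearance** at a node is the distance to the nearest atom surface,
  capped at 10³ Å in empty space;
* the tunnel is the lowest-cost 26-connected path between the caller's two
  anchor coordinates (e.g. the ALDH catalytic cysteine sulphur and the ADH
  metal-site histidine centroid). The stated edge cost,
  `step × 1/(clearance − r_probe + ε)` with ε = 0.1 Å, leaves open which
  endpoint's clearance applies; it is symmetrised as the mean of the two
  endpoint reciprocals so the graph is undirected and the path independent
  of traversal direction.

Unreachable anchors yield a distinguished "no tunnel" result, not an error;
anchors inside an atom are an error. Per-point radii are true clearances,
so they can never exceed the brute-force distance to the nearest atom
surface — a property the tests check directly.

**Enclosure.** A centerline point is *exposed* when bulk solvent reaches
its immediate surroundings: a 6-connected flood fill from the boundary of
the padded grid over open nodes that are **outside** the channel (further
than the local tunnel radius from the centerline) reaches a node within
`local radius + √3·spacing` of that point. 6-connectivity is used for the
solvent fill — diagonal moves could leak through voxel corners that no
probe could pass. The hemispherically capped phantom tube is 100% enclosed
under this definition, and carving a probe-passable window exposes exactly
the window-adjacent points — the desk-scale mirror of the published
contrast between the sealed extended channel and the leaky compact one.

## Composition, enrichment, conservation

* **Enrichment**: `log2fc(a) = log2[((c_a+α)/(C+20α)) / ((p_a+α)/(P+20α))]`
  with α = 0.5 (Jeffreys). The pseudocount matters: a channel containing a
  single lysine — or none — must produce a large negative but finite value,
  not −∞. α is exposed everywhere it is used.
* **Column conservation** is the percentage of rows (reference included)
  matching the reference residue, gaps counting as mismatches; positions
  are reported in ungapped reference coordinates. Counting gaps as
  mismatches is the conservative reading where the original hand count is
  unspecified.
* **Pairwise identity** divides identical columns by aligned columns
  excluding terminal-gap columns. Alternative denominators (all columns,
  shorter sequence) are returned alongside, since round published
  percentages rarely state their denominator.
* **Set homology** ("are the channel residues the same in both species")
  is implemented as strict identity over alignment-mapped position pairs,
  with unmapped positions counted as non-identical; whether published
  "homology" means identity or similarity classes is unstated, so a
  BLOSUM62-positive similarity percentage is reported alongside and the
  identity number is the headline.

## Trajectory channeling metrics

Escape is operationalised as: minimum ligand–protein heavy-atom distance
> 10 Å sustained for ≥ 5 consecutive frames; residence time is
`dt × first frame of that excursion` (frames 1-based). "Escape to solvent"
has no canonical numeric criterion, so both thresholds are arguments and
are echoed into all outputs. Brief excursions shorter than the sustain
window do not terminate residence.

Censoring is handled conservatively: a trajectory that never
escapes contributes its full length, and any ensemble containing a censored
replicate reports its mean as a **lower bound** rather than applying a
survival estimator — with triplicate ensembles, Kaplan–Meier machinery
would suggest precision the data cannot support. Hydrogen-bond occupancy
uses the distance-only criterion (heavy atoms; no hydrogens at analysis
level). Published residence times from cluster-scale MD are explicitly
non-targets: the module is validated against synthetic ground truth where
the escape frame is known exactly.

## Ultrastructure statistics

The Mann–Whitney U statistic is computed from midranks. For n₁+n₂ ≤ 12 the
two-sided p is exact: all `choose(n1+n2, n1)` label assignments are
enumerated (ties included naturally), the smaller tail doubled and capped
at 1 — the convention matching `wilcox.test`, against which the
implementation is cross-checked on untied data. Larger samples use the
normal approximation with tie correction and a 0.5 continuity correction.
Mean-based summaries are reported alongside even though the test addresses
stochastic dominance, because length differences are customarily quoted as
mean shifts; the >100 nm tail fraction is reported because the loss of long
filaments is the feature that drives such shifts. Conformation proportions
carry Wilson 95% intervals, which behave at 0 and 1 where Wald intervals
collapse.

## Synthetic data: the stated world

The generators emulate the statistical and geometric structure the analyses
assume — not the AdhE fold, sequence, or force field:

* **Toy multimer**: designed Lys–Asp bridges at 3.7 Å (inside the 4.0 Å
  salt-bridge cutoff, outside the 3.5 Å hydrogen-bond cutoff, so the two
  truth sets never overlap) and Ser–Gly hydrogen bonds at 2.9 Å, each on a
  well-separated site with ±0.05 Å seeded jitter. Truth is re-derived at
  generation time by an independent brute-force scan; a request the
  geometry cannot honour is an error.
* **Channel phantom**: single-layer carbon shell (uniform 1.7 Å radius —
  one radius keeps clearance arithmetic exact) around a straight or gently
  curved centerline, wall spacing ≈ 1.2–1.5 Å so a 1.4 Å probe cannot leak,
  hemispherical end caps so "enclosed" is well-defined, optional
  probe-passable window and optional mid-tube bulge for the widest-point
  check.
* **Trajectories**: a reflected random walk inside a recorded tube with a
  constant per-frame escape hazard (escape = permanent departure far beyond
  the threshold) and a programmed Bernoulli contact with a designated wall
  atom. Defaults (dt 0.1 ns, 2000 frames → 200 ns) match the published
  simulation scale.
* **Lengths**: positive-truncated normals, native 80 ± 25 nm vs exogenous
  60 ± 25 nm at n = 1250 per group — the published measurement count, a
  20 nm mean shift as reported, and a spread chosen so that a realistic
  fraction of native filaments exceeds 100 nm while the exogenous group
  largely does not. The raw published measurements are not available, so
  these moments are the stated world, fixed once.

A green test therefore establishes that each algorithm recovers known
ground truth under its stated assumptions — it does not establish agreement
with any specific deposited structure, which is exercised separately by the
four deposited-structure benchmarks (red unless the user supplies the
files; this environment cannot fetch them).

## Numerical choices and degenerate inputs

* Sphere quadrature and grid ordering are fully deterministic; reruns of
  any analysis (and of `runReport()`) are byte-identical.
* Clearance softening ε = 0.1 Å bounds edge costs as clearance approaches
  the probe radius; the 10³ Å clearance cap keeps costs finite in empty
  space without affecting path choice.
* Ties: widest point returns the first maximum; grid paths break ties by
  node order; duplicate contact pairs collapse to the minimum distance.
* Degenerate inputs fail loudly: empty structures or selections, collinear
  superposition sets, ragged alignments (named row), inconsistent
  trajectory frames (named frame), overlapping chain groups, zero-count
  groups.

## Known limitations

* The tunnel finder is a grid approximation: centerlines are accurate to
  about one grid spacing and the cost function only imitates the
  wide-lumen preference of Voronoi methods. Externally computed centerlines
  can be wrapped in a `Tunnel` object for exact interoperability.
* Contact counts depend on the stated cutoffs; only the extended > compact
  orderings, not exact published counts, should be considered robust.
* SASA is O(n²) in atoms per evaluation; full-filament models take minutes,
  not seconds.
* The Mann–Whitney exact method enumerates and is limited to small samples
  by design; the approximation is corrected but still an approximation in
  the extreme tails.
* No π-stacking or cation–π detection, no protonation assignment, no
  symmetry-mate generation, no map handling, no force-field simulation.
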