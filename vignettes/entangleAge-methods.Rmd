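---
title: "Detecting native lasso entanglements and linking them to age-associated structural change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting native lasso entanglements and linking them to age-associated structural change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entangleAge)
```

## The scientific problem

A non-covalent lasso entanglement (NCLE) is a geometric motif in a folded
protein: a stretch of backbone forms a loop that is closed not by a disulfide
or other covalent bond but by an ordinary native contact, and one of the
terminal tails threads through that loop. Proteins carrying native NCLEs can
misfold by *failing to thread* — the loop closes, the tail stays outside —
producing long-lived, near-native misfolded states that are hard for
chaperones to recognise. `entangleAge` implements an analysis chain that asks
whether this class of misfolding leaves a statistical signature in a
proteome-wide limited-proteolysis mass-spectrometry (LiP-MS) comparison of
young and replicatively aged yeast cells, and provides the simulation and
surface-accessibility machinery to rationalise the signal mechanistically.

The pipeline has four layers:

1. **Geometry** — detect NCLEs in structures by discretized Gaussian linking
   integrals (`gaussLinking`, `detectNcles`), localize crossing residues,
   exclude slipknots, collapse degenerate calls (`clusterNcles`), and emit
   entangled-region residue masks (`entangledRegionMask`).
2. **Proteolytic evidence** — classify proteins and residues as exhibiting
   age-associated structural change from a quantified peptide table
   (`isSignificant`, `classifyProteinChange`, `residueAlterationMask`).
3. **Association statistics** — crude odds ratios with Woolf intervals and
   Fisher tests (`contingency`), length-adjusted logistic odds ratios
   (`adjustedOR`), bootstrap median intervals, the Brunner–Munzel test, and
   transcript-normalized abundance calls (`abundanceCalls`).
4. **Mechanism** — a C-alpha structure-based (Gō-type) model with a
   thermal-unfold/temperature-quench protocol (`buildGoModel`, `runQuench`),
   per-frame order parameters Q and G, KMeans++/PCCA+ state clustering,
   misfolding probability, and a Shrake–Rupley SASA permutation test that
   asks whether simulated misfolded states are consistent with the observed
   proteolysis changes (`stateConsistency`).

Every layer has a synthetic generator with planted ground truth, so the whole
chain runs and is tested without any external download.

## Linking integrals and NCLE calls

The chain of N Cα positions $r_l$ is reduced to segment midpoints
$R_l = (r_l + r_{l+1})/2$ and bond vectors $dR_l = r_{l+1} - r_l$. For a
candidate loop closed by the native contact $(i, j)$, the linking of each
terminal tail with the loop is

$$ g = \frac{1}{4\pi}\sum_{m}\sum_{n=i}^{j-1}
  \frac{R_m - R_n}{|R_m - R_n|^3}\cdot(dR_m \times dR_n), $$

with $m$ running over $6..i-5$ for the N tail and $j+6..N-5$ for the C tail:
the first and last five residues and the five residues flanking the loop are
excluded, and an empty range contributes exactly zero. A loop is called
entangled when $|g_N| \ge 0.6$ or $|g_C| \ge 0.6$. We apply the threshold to
the *magnitude*: $g$ is signed by threading chirality, and a left-handed
thread is as entangled as a right-handed one. Candidate loops are exactly the
native contacts of the 4.5 Å heavy-atom contact map (pairs separated by more
than three residues).

Crossing residues are found from the cumulative partial-linking profile along
the tail: each passage of the profile through a half-integer level is a
crossing, signed by the step. This replaces the external topology package
used in the original annotation workflow with a self-contained construction
that we validate against fixtures of known geometry; it is an approximation,
and tails whose crossings cancel (opposite signs — a thread that retracts,
i.e. a slipknot) are excluded from NCLE calls.

Degenerate NCLEs — one physical threading reported by several neighbouring
loop-closing contacts — are clustered: calls sharing crossing signs with all
crossing residues within ±5 sequence positions join a cluster, and the member
with the shortest loop (ties: smallest $i$) represents it. The ±5 window and
the shortest-loop rule are our concretization of the clustering described
only by citation in the source annotation protocol; they are deterministic
and order-independent.

The entangled *region* of a protein is the union of (a) residues within ±3
sequence positions of any loop-closing or crossing residue of a
representative NCLE and (b) residues with any heavy atom within 4.5 Å of
those key residues.

## LiP-MS classification

A peptide marks an age-associated structural change when its abundance
differs between aged and young cells with $|\text{fold change}| > 5$ and
adjusted $p < 0.05$ (both strict). A protein changes iff at least one of its
peptides does; a protein with no observed peptides is *not observed*, never
FALSE. Altered proteolytic cleavage sites map to residues as: the
proteinase-K-generated terminus for half-tryptic peptides, the central
residue for tryptic ones (floor of the midpoint for even-length spans — the
convention is not dictated by the data, and the ±3-residue buffer absorbs
it). The stored fold-change scale (linear vs log2) is a reader flag because
peptide tables in the wild use both; thresholds always apply to the linear
ratio.

## Association models

The crude association between NCLE presence and structural change is the 2×2
cross-product odds ratio with a Woolf (logit-scale) interval
$\exp(\ln\text{OR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$ and a two-sided Fisher
exact p-value. The Woolf interval reproduces both published intervals from
the published counts to the printed precision, which is why it is the
packaged default; zero cells leave the OR flagged undefined unless the
Haldane correction is requested explicitly.

Protein length confounds the crude comparison — longer chains both contain
more NCLEs and accumulate more mapped peptides — so the adjusted analysis
fits $\mathrm{logit}\,p = \beta_0 + \beta_1 E + \beta_2 L$ with $E$ the
binary exposure and $L$ the standardized length, and reports
$\exp(\beta_1)$ with a Wald interval. The same model serves the residue-level
enrichment question with $E$ = "residue in the entangled region". The
confounded mode of `genPeptideTable` demonstrates the point: length drives
both exposure and outcome, the crude OR is visibly biased, and the logistic
fit recovers the planted $\beta_1$.

`brunnerMunzel` implements the rank-based test of stochastic equality used
to compare misfolding-probability distributions; it is written from the
standard formulation (no installed R package provides it) and is checked
against a permutation oracle and for null calibration. Complete separation
returns an infinite statistic with a 0/1 p-value; all-tied data are an
error.

## The Gō model and quench protocol

Each residue is one bead at its Cα position. The force field is the
canonical structure-based recipe: harmonic bonds (50 kcal/mol/Å²) and angles
(30 kcal/mol/rad²) at native values, 1- and 3-fold cosine dihedrals
(1.0/0.5 kcal/mol) around the native torsions, a 12–10 well of uniform depth
ε on every native pair at its native distance, and a purely repulsive
$r^{-12}$ excluded volume (σ = 4 Å) elsewhere. For the packaged Cα-only
fixtures the native pairs come from an 8 Å Cα-distance map — the standard
Cα proxy for the 4.5 Å heavy-atom criterion, which is not computable without
side-chain atoms. ε = 0.8 kcal/mol is calibrated once so that the packaged
40-residue two-helix fixture is stable at 300 K and unfolds at 600 K; the
exact bonded parameters of the cited production force field are not printed
in the source, so quantitative misfolding fractions from this compatible
stand-in are not expected to match production values.

Dynamics is BAOAB Langevin integration (15 fs step, friction 0.05 ps⁻¹,
masses 110 g/mol) with a deterministic per-seed RNG; kinetic temperature is
measured at mid-step velocities, where the middle scheme is unbiased, and
microcanonical runs (γ = 0) conserve energy to <0.5% at a quartered step.
The quench protocol runs 15 ns at 600 K from the native state and then the
quench leg at 300 K, saving every 5000 steps, mirroring the production
schedule; desk-scale defaults are 10 trajectories of 50 ns (the production
50 × 1.5 μs is cluster-scale and config-reachable). Mirror-image
trajectories — a real artifact of Cα models, whose dihedral terms only
weakly penalize the inverted chirality — are flagged by comparing the median
dihedral sign over natively helical segments in the trajectory tail against
the native structure, a documented heuristic standing in for the original
protocol.

Folding checks are read on the mean Q over the trailing third of a leg
rather than one final frame: Q is an instantaneous, thermally fluctuating
observable, and the leg-mean is the stable reading of "unfolds" (mean
Q < 0.3 at 600 K) and "stays folded" (mean Q > 0.9 at 300 K).

## Q, G, state clustering, misfolding probability

Per frame, $Q$ is the fraction of native pairs whose Cα distance is at most
1.2× the native distance (boundary inclusive, $\Theta(0)=1$), and $G$ is the
fraction of native contacts whose loop's recomputed $g_N$ or $g_C$, rounded
to the nearest integer, differs from the rounded native reference. Rounding
is deliberate: raw $g$ fluctuates thermally, and the integer change is the
topological event. $G$ sums over the full reference contact set whether or
not a contact is formed in the frame.

Frames are standardized on (Q, G) and clustered into 100 microstates by
KMeans++ (the ++ seeding is implemented here; Lloyd refinement is
`stats::kmeans`), a lagged transition-count matrix (default lag 10 saved
frames, counted within trajectories, small pseudocount, row-normalized) is
lumped by an inner-simplex PCCA+ into macrostates, and the macrostate count
comes from configuration or, in "auto" mode, the largest spectral gap — a
reproducible stand-in for the source protocol's visual inspection of the
log-probability plot. The native macrostate is the one with the highest mean
$Q - G$.

Misfolding probability over an analysis window (the final 200 ns in the
production protocol) is $P_{mis} = N_{mis}/(N_{native}+N_{mis}) \times 100$:
frames of the native macrostate count toward $N_{native}$; frames of
non-native macrostates with $Q \ge$ the near-native floor count toward
$N_{mis}$. The floor defaults to 0.6 — the source labels states with
$Q \approx 0.9$ "near-native" but never states a floor — and grossly
unfolded frames ($Q$ below the floor in non-native states) count toward
neither, the stricter of the two readings of the denominator.

## SASA consistency

Solvent accessibility is Shrake–Rupley with a deterministic golden-spiral
point set (256 points, probe 1.4 Å): van der Waals radii per element for
atomic models, or a uniform 3.4 Å sphere per residue for bare Cα traces (the
native path for coarse-grained frames; outputs carry a label saying which
approximation produced them). All-atom reconstruction of coarse-grained
frames is out of scope — the Cα-sphere path is a documented approximation,
not a replacement claim. Per altered cleavage site, the window mean over ±5
residues is compared between each non-native state ensemble and the native
ensemble with a two-sided permutation test on the absolute mean difference,
$p = (1 + \#\{|\Delta| \ge |\Delta|_{obs}\})/(n_{perm}+1)$ (never zero;
pool sorted so the p-value is exactly symmetric in the two ensembles). All
(state, site) p-values of one protein form a single BH family — the source
reports one adjusted p per state–peptide pair without naming the family, so
the choice is explicit and configurable — and a state is consistent when any
of its sites survives at adjusted $p < 0.05$.

## Synthetic generators: what they emulate, and what they do not

* `genLoopCurve` plants exact linking numbers (0, ±1, ±2) with a
  circle-plus-tail geometry whose closure gap is ~2 Å and whose threading
  passes extend four loop radii, so the discretized $|g|$ sits within 0.05
  of the planted integer. It emulates topology, not protein energetics.
* `genMiniProtein` provides a foldable 40-residue two-helix bundle and a
  58-residue contact-closed threaded loop with its planted loop and crossing
  residue. Both are idealized backbones: they exercise detection and
  simulation logic but carry no side chains, no sequence heterogeneity.
* `genPeptideTable` emulates the joint structure exposure/outcome/length and
  the peptide evidence layer, with marginal prevalences defaulting to the
  observed scale (74.7% entangled; 21.8% vs 12.3% changed). It does not
  model mass-spectrometric noise beyond binary significance.
* `genQgSeries` is a Markov-switching Gaussian mixture on (Q, G) — it
  emulates metastable-state statistics, not dynamics on an energy surface.
* `genSasaEnsembles` plants window-mean shifts on iid Gaussian per-residue
  SASA (mean 60 Å², SD 8 Å²); real ensembles have correlated residues.

Passing tests on these fixtures therefore demonstrates correctness of the
algorithms and calibration of the statistics under the stated generative
assumptions — not that real aged-proteome data would reproduce any specific
published effect size.

## Numerical choices and problem sizes

Tolerances and sizes used by the test suite and the acceptance script, all
chosen as desk-scale analyses: linking oracle comparisons at 1500-point
densification; 25 + 25 mini-protein fixtures for detection recall/precision;
100 replicates of n = 20,000 for logistic parameter recovery; 20 seeds each
for the 600 K/300 K folding checks (15 ns and 2 ns legs); 30,000 frames,
60 microstates for state-clustering recovery; 2,000/1,000 replicates for
rank- and permutation-test null calibration with 399 permutations per test;
500 null proteins and 100 planted-shift seeds for the consistency stage.
Bootstrap median intervals default to 10⁶ resamples in production use and
smaller counts in tests. Degenerate inputs are handled as stated in the
function documentation: empty tail windows give exactly zero linking,
collinear coordinate sets return the rod limit of asphericity, zero
permutation difference returns p = 1, and separation in the logistic fit is
flagged rather than silently reported.

## Known limitations

* Crossing-residue localization via half-integer passages of the partial
  linking profile can mislocalize by a residue or two when the tail grazes
  the loop plane; the ±3/±5 buffers downstream absorb this.
* The Gō parameters are a compatible stand-in; absolute misfolding
  probabilities are not comparable to production-scale published medians.
* PCCA+ on few frames or weakly metastable data is sensitive to the lag;
  the lag is an explicit parameter (default 10 saved frames).
* The Cα-sphere SASA path reproduces window-mean *differences* well but not
  absolute atomic SASA values.
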