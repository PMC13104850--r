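# entangleAge

Native non-covalent lasso entanglements (NCLEs) and age-associated
structural change in proteomes.

An NCLE is a backbone loop closed by an ordinary native contact and pierced
by a terminal tail. Proteins carrying native NCLEs have an extra way to
misfold — the loop closes but the tail never threads — and the resulting
states are soluble, long-lived and nearly native, so they can slip past
chaperone quality control and accumulate as cells age. `entangleAge`
implements the full analysis chain for testing whether such entanglements
are statistically associated with age-related structural changes measured by
limited-proteolysis mass spectrometry (LiP-MS), and for rationalising the
association mechanistically with coarse-grained refolding simulations:

* **Entanglement detection.** Discretized Gaussian linking integrals over
  the Cα trace: for a loop closed by contact (i, j), the linking of each
  tail is `g = (1/4π) Σ_m Σ_n (R_m − R_n)/|R_m − R_n|³ · (dR_m × dR_n)`,
  with a call when |g_N| ≥ 0.6 or |g_C| ≥ 0.6; crossing-residue
  localization, slipknot exclusion, degenerate-call clustering and
  entangled-region masks.
* **LiP-MS classification.** Peptide significance (|fold change| > 5,
  adjusted p < 0.05), protein-level change calls, and cleavage-site residue
  masks with a ±3 buffer.
* **Association statistics.** 2×2 odds ratios with Woolf CIs and Fisher
  tests; length-adjusted logistic odds ratios
  (logit p = β₀ + β₁E + β₂L); bootstrap median CIs; the one-sided
  Brunner–Munzel test; transcript-normalized abundance-increase calls.
* **Simulation.** A Cα Gō-type model (12–10 native wells, cosine
  dihedrals) with a BAOAB Langevin thermal-unfold/quench protocol, in
  compiled code; fraction of native contacts Q, entanglement-change
  fraction G, KMeans++/PCCA+ state clustering, misfolding probability
  P_mis = N_mis/(N_native + N_mis) × 100.
* **SASA consistency.** Shrake–Rupley accessibility, ±5-residue window
  means at altered cleavage sites, permutation tests with BH adjustment.
* **Synthetic data.** Seed-deterministic generators with planted ground
  truth for every stage (threaded curves, mini-proteins, peptide tables,
  (Q,G) series, SASA ensembles), so the whole pipeline runs with no
  downloads.

## Worked example

Detect the planted entanglement in a synthetic mini-protein and reproduce a
published protein-level association from its printed counts:

```r
library(entangleAge)

mp <- genMiniProtein("entangled_hairpin", seed = 1)
cm <- heavyAtomContacts(mp$structure)          # 4.5 A heavy-atom contacts
ncles <- clusterNcles(detectNcles(mp$structure, cm))
Filter(function(x) x@representative, ncles)[[1]]
#> NCLE loop (5, 20) gN=0.00 gC=0.89, 1 crossing(s) [representative]

contingencyFromCounts(368, 1318, 70, 500)
#> 2x2 table  a=368 b=1318 c=70 d=500
#> OR = 1.99  (95% CI [1.51, 2.63]), Fisher p = 3.25e-07
```

The detected loop (residues 5–20, C-tail linking 0.89) is exactly the
planted threading. The 2×2 analysis says proteins with at least one native
NCLE have about twice the odds of showing an age-associated structural
change. Length confounds such comparisons — longer proteins have more
entanglements *and* more mapped peptides — which the logistic model
untangles on synthetic data where the truth is known:

```r
fx <- genPeptideTable(nProteins = 20000, beta = c(-2, log(2), 0.5),
                      confounded = TRUE, emitPeptides = FALSE, seed = 7)
oddsRatio(contingency(fx$proteins$entangled, fx$proteins$changed))
#> [1] 3.167002   # crude OR, biased upward by the length confounder
adjustedOR(fx$proteins$changed, fx$proteins$entangled, fx$proteins$length)
#> logistic fit: adjusted OR = 1.96 (95% CI [1.79, 2.15]), p = 1.02e-47
```

The planted exposure effect is exp(β₁) = 2: the crude estimate (3.17) is
badly confounded, the adjusted one recovers it.

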