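# gabamod

Quantitative analysis of allosteric modulation of GABA_A receptors under
the two-state (resting ⇌ active) cyclic co-agonist model, for
electrophysiologists working with *Xenopus* oocyte voltage-clamp data:
α7-nicotinic-receptor PAMs (NS-1738, PAM-2), anesthetics (propofol,
etomidate) and neurosteroids acting through the transmembrane
intersubunit-interface sites of the α1β2γ2L receptor and its mutants.

## The model

Each ligand biases the resting ⇌ active equilibrium independently. With a
background open probability `P_bg`, a compound at concentration `L`, with
resting-state dissociation constant `K_R`, gating efficacy
`c = K_active / K_resting` and `N` imposed binding sites:

    P_A = 1 / (1 + ((1 − P_bg)/P_bg) · [(1 + L/K_R) / (1 + L/(K_R·c))]^N)

At a saturating concentration the bracket collapses to `c^N`, and the
inversion

    c = [ (1/P_A − 1) / ((1 − P_bg)/P_bg) ]^(1/N)

recovers the efficacy from a single background/modulated pair. The total
active-state stabilization energy is `ΔG = N·RT·ln(c)` (kcal/mol,
negative = potentiator); unlike fold-potentiation — which shrinks as the
background rises — `ΔG` is comparable across cells, compounds and site
counts. Mutant-cycle analysis compares the wild-type `ΔG` with the summed
mutation-induced losses `ΔΔG = ΔG_mut − ΔG_wt` across interfaces: additive,
independent sites satisfy `ΔG_wt = −Σ ΔΔG_i`.

Open probabilities come from per-cell current anchors: 200 µM picrotoxin
(all channels blocked, `P_A = 0`) and 1 mM GABA + 50 µM propofol (all
activated, `P_A = 1`). Receptors with constitutive activity above 0.02 are
analyzed by direct activation (modulator vs holding current); quiet
receptors by potentiation of a low-GABA response.

## Worked example

```r
library(gabamod)

# per-mutation energy changes for NS-1738 across the three interfaces,
# from the bundled reference group summaries
tab <- reference_summaries("pam")
rep_ns <- mutant_cycle_report(
  tab, compound = "NS-1738", wildtype = "alpha1beta2gamma2L",
  mutants = c("beta2(F289T)", "alpha1(Y293C)", "gamma2L(F304C)"))
print(rep_ns)
```

```
Mutant cycle: NS-1738, wild type alpha1beta2gamma2L
  beta2(F289T)         ddG   1.92 [ 1.50,  2.34] kcal/mol
  alpha1(Y293C)        ddG   1.01 [ 0.86,  1.16] kcal/mol
  gamma2L(F304C)       ddG   1.44 [ 1.17,  1.71] kcal/mol
  sum                  ddG   4.37 [ 3.85,  4.89] kcal/mol
Additivity test (NS-1738):
  sum of ddG = 4.37 [3.85, 4.89] kcal/mol
  -dG(wild type) = 0.70 kcal/mol
  -> NOT additive: interval excludes -dG(wild type)
```

The summed losses (4.37 kcal/mol) far exceed the wild-type stabilization
(0.70 kcal/mol): the interval excludes `−ΔG_wt`, so the interface sites are
energetically coupled rather than independent.

A synthetic study with known ground truth runs the same pipeline
end-to-end:

```r
spec <- sim_preset("alpha1beta2gamma2L", "NS-1738", seed = 11)
est <- efficacy_summary(simulate_cells(spec))$summary
est[, c("n", "modulation_mean", "c_mean", "c_sd", "mean_dG", "sd_dG")]
#    n modulation_mean   c_mean       c_sd    mean_dG      sd_dG
#   25         299.763 0.548844 0.02268517 -0.7118102 0.04893127
```

25 simulated oocytes at wild-type conditions recover the ground-truth
efficacy (c ≈ 0.55, ΔG ≈ −0.70 kcal/mol) from noisy per-cell measurements.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/gabamod-cli.R` (subcommands `simulate`, `efficacy`,
`mutant-cycle`, `curve`, `protect`).

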