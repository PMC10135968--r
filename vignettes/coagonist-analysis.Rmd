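---
title: "Two-state co-agonist analysis of GABA-A receptor modulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state co-agonist analysis of GABA-A receptor modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gabamod)
```

## The model and its assumptions

gabamod analyzes receptor modulation in the two-state cyclic co-agonist
framework: the receptor occupies a resting or an active conformation, and
every bound ligand shifts the equilibrium by an independent energetic
increment. For a compound with resting-state dissociation constant
$K_R$, efficacy $c = K_{active}/K_{resting}$ and $N$ imposed binding
sites, the open probability in the presence of concentration $L$ is

$$P_A = \left[1 + \frac{1-P_{bg}}{P_{bg}}
  \left(\frac{1 + L/K_R}{1 + L/(K_R c)}\right)^{N}\right]^{-1}.$$

The framework assumes (i) a single concerted gating equilibrium — no
intermediate conductances or desensitized states enter the arithmetic;
(ii) equivalent, independent binding sites for a given compound, so the
occupancy factor enters as a power $N$; and (iii) measurements at
steady state. All analyses in the package work at a *saturating*
concentration, defined operationally as $\geq 1000 \times K_R$, where the
occupancy bracket collapses to $c^N$ and the state function can be
inverted in closed form:

$$c = \left[\frac{1/P_{A} - 1}{(1-P_{bg})/P_{bg}}\right]^{1/N}.$$

`state_function()` evaluates the general form, mostly as a consistency
check: at $1000 \times K_R$ it agrees with `saturating_state_function()`
to about $3\times10^{-4}$ relative (for $c \geq 0.05$; tests assert
$10^{-3}$), while the inversion `efficacy_from_activation()` is an exact
right-inverse of the saturating form (tested to $10^{-9}$ relative across
$c \in [0.01, 100]$, $P_{bg} \in [0.001, 0.999]$, $N \in \{1,2,4\}$).

The total stabilization energy is $\Delta G = N\,RT\,\ln c$ (kcal/mol).
Fold-potentiation, in contrast, depends strongly on the background:
`fold_potentiation_curve()` shows that a compound with $c = 0.100$
potentiates a $P_{bg} = 0.05$ response almost 17-fold but does nearly
nothing at $P_{bg} = 0.9$. This ceiling effect is why groups are compared
on $c$ and $\Delta G$, never on fold-potentiation measured at different
backgrounds.

## Parameters and conventions

* **RT** — defaults to $1.987\times10^{-3} \times 298.15 = 0.5924$
  kcal/mol. The recordings the model describes are performed near room
  temperature; the printed reference energies are consistent with
  297–298 K but per-cell averaging prevents pinning the value more
  precisely, so the temperature is configurable metadata
  (`energy_context()`) and is echoed into every manifest.
* **Site counts N** — by convention 2 for the α7-PAMs (NS-1738, PAM-2),
  4 for propofol, 2 for etomidate and the neurosteroid 3α5βP. The
  pipeline keeps a compound → N map in `run_config()`; a compound without
  an entry is an error rather than a silent default.
* **Probability boundaries** — measured probabilities of exactly 0 or 1
  (a response equal to an anchor) would produce infinities; they are
  replaced by `eps = 1e-6` / `1 - eps`. Interior values are never
  altered: clamping valid data would bias the efficacy estimate, and the
  exact-inversion property would be lost. Values outside [0, 1] are
  rejected as schema errors.
* **Protocol thresholds** — receptors with constitutive open probability
  strictly above 0.02 are analyzed by direct activation (the
  constitutive level is the control); at or below 0.02 by low-GABA
  potentiation. Below 0.01 the low-GABA background is used without
  constitutive correction. In the 0.01–0.02 band no correction rule is
  defensible from the available evidence — every reference analysis
  either ignored the correction or switched protocol — so the background
  is used uncorrected and the cell is flagged (`band_flag`) for audit;
  the flag count surfaces in the efficacy report and manifests.
* **Confidence intervals** — normal approximation with $z = 1.96$,
  $SE_{\Delta\Delta G} = \sqrt{sd_{wt}^2/n_{wt} + sd_{mut}^2/n_{mut}}$.
  A t-quantile would widen the intervals by ~5–10% at the group sizes
  involved (n = 5–25); the z convention is the one that reproduces the
  bundled reference intervals exactly and is checked against a
  Monte-Carlo percentile oracle (100,000 draws, agreement within
  0.02 kcal/mol).

## Mutant-cycle additivity

`ddg()` forms $\Delta\Delta G = \Delta G_{mut} - \Delta G_{wt}$ per
interface from group summaries (mean, SD, n of *per-cell* energies —
group means of probabilities are never pushed through the nonlinear
transform). `additivity_sum()` adds point estimates and variances;
`additivity_test()` declares additivity when $-\Delta G_{wt}$ falls
inside the summed interval (boundary-inclusive).

Two summation conventions exist when every $\Delta\Delta G$ shares the
same wild-type group. The default treats the components as independent —
each component variance already contains the wild-type term, and the sum
adds them as they stand. A covariance-aware mode
(`additivity_sum(..., covariance_aware = TRUE)`) instead counts the
shared wild-type variance once as $k^2\,\mathrm{Var}(\bar{G}_{wt})$ for
$k$ components, which is the correct propagation under a literally shared
control mean and yields somewhat wider intervals. The default is the
independence convention because it is the one under which the summed
interval is consistent with the per-pair intervals as published
conventions in this field go; the mode switch exists for methodological
comparison and sensitivity analysis.

```{r mutant-cycle}
tab <- reference_summaries("pam")
mutant_cycle_report(tab, compound = "NS-1738",
                    wildtype = "alpha1beta2gamma2L",
                    mutants = c("beta2(F289T)", "alpha1(Y293C)",
                                "gamma2L(F304C)"))
```

## Protection assays

The SCAMP quantification works on the ratio of low- to high-GABA
responses per cell, which cancels expression level and rundown. The fold
change of that ratio across a labeling exposure measures the functional
effect of covalent modification; `protection_index()` compares fold
changes between reagent-alone and reagent-plus-ligand groups with a
one-sided Welch test (protection = significantly smaller fold change in
the protected group, default $\alpha = 0.05$). The one-sided form is
deliberate: protection is a directional hypothesis, and the flag's
false-positive rate under the null then equals $\alpha$ (verified by
simulation in the test suite). Omnibus comparisons across several
protectants are left to standard ANOVA machinery; only the ratio/fold
quantification is bespoke.

## The synthetic-data generator

`simulate_cells()` emulates the statistical structure the analysis
assumes, with defaults matching the reference wild-type conditions
(background $P_A$ 0.05 ± 0.03 across cells, group sizes 5–25 via
`sim_preset()`, efficacies spanning ~0.1–3):

1. per-cell background and constitutive probabilities are drawn from
   truncated normals (windows (0.005, 0.95) and (1e-4, 0.95); rejection
   sampling, exact within the window, with a 10,000-round cap);
2. the modulated probability follows the saturating state function with
   the ground-truth efficacy;
3. every *measured* probability gets multiplicative noise
   $\mathcal{N}(1, cv)$ with $cv = 0.05$ by default. Noise is placed on
   probabilities rather than currents because the reference group SDs of
   $c$ scale with $c$, which multiplicative probability noise reproduces;
   current-level noise is available through `simulate_amplitudes()`,
   which also exercises the anchor-normalization round trip;
4. the protocol is chosen from the *measured* constitutive activity,
   as an experimenter would.

All randomness flows from the spec's single seed; runs are bit-identical.
What the generator does **not** emulate: desensitization and wash
kinetics, series-resistance and leak artifacts, correlated drift within a
recording day, and sub-saturating concentrations. Passing recovery tests
therefore validate the estimation arithmetic and its statistical
behavior, not the experimental assumptions themselves.

Ground-truth efficacies for presets are derived from the reference group
*energies* (`c_true = exp(mean_dG / (N RT))`) rather than the printed
mean $c$, because the per-cell mean of $c$ and the per-cell mean of
$\Delta G$ are not linked by the nonlinear transform; targeting the
energy makes simulated $\Delta\Delta G$ sums land on the reference
ground truth (4.37 vs 0.70 kcal/mol for NS-1738), which the power checks
exploit.

## Problem sizes and numerical choices

The test suite simulates at the reference group sizes (5–25 cells; 200
cells for bias checks; 200 replicate studies for the power check) — sizes
chosen to mirror the study design the generator emulates. Degenerate
inputs are rejected early: coincident anchors, probabilities outside
[0, 1], groups with n < 2, compounds without a site count, empty mutant
selections. Ties at the additivity boundary count as additive
(the interval is closed). Report rounding (c to 3 decimals, ΔG to 2)
happens only in `print()` methods; machine-readable outputs keep full
precision.

## Known limitations

* $K_R$ is never fitted — all analyses assume a single near-saturating
  concentration; concentration–response fitting is out of scope.
* The normal-approximation intervals ignore the small-sample t
  correction (documented above) and the group summaries assume
  approximately normal per-cell energies.
* Peak/steady-state extraction from raw current traces is upstream of
  this package; inputs are already-extracted amplitudes.
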