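#' gabamod: two-state co-agonist analysis of GABA-A receptor modulation
#'
#' Tools for analyzing allosteric modulation of GABA-A receptors under the
#' two-state (resting-active) cyclic co-agonist model: open-probability
#' normalization of oocyte currents, gating-efficacy (c) and stabilization
#' energy (delta-G) estimation, mutant-cycle additivity analysis with
#' propagated confidence intervals, substituted-cysteine protection metrics,
#' and a synthetic data generator for end-to-end validation.
#'
#' @keywords internal
"_PACKAGE"

# Gas constant in kcal/(mol*K); with T = 298.15 K this gives the RT used
# throughout unless the user supplies another temperature.
.R_KCAL <- 1.987e-3
.DEFAULT_TEMPERATURE_K <- 298.15

#' Thermodynamic context for free-energy calculations
#'
#' Bundles the thermal energy `RT` (kcal/mol) with the temperature assumption
#' it was derived from, so every energy reported downstream carries its
#' convention. The default corresponds to 298.15 K (RT = 0.5924 kcal/mol).
#'
#' @param temperature_K absolute temperature in kelvin (> 0).
#' @param RT thermal energy in kcal/mol; normally derived from
#'   `temperature_K`, but may be given directly (then `temperature_K` is
#'   recorded as metadata only).
#' @return An object of class `energy_context`: a list with elements `RT`,
#'   `temperature_K` and `R` (kcal/mol/K).
#' @examples
#' ctx <- energy_context()
#' ctx$RT
#' @export
energy_context <- function(temperature_K = .DEFAULT_TEMPERATURE_K,
                           RT = .R_KCAL * temperature_K) {
  if (!is.numeric(RT) || length(RT) != 1L || !is.finite(RT) || RT <= 0) {
    stop("'RT' must be a single positive number (kcal/mol)", call. = FALSE)
  }
  structure(
    list(RT = RT, temperature_K = temperature_K, R = .R_KCAL),
    class = "energy_context"
  )
}

#' @export
print.energy_context <- function(x, ...) {
  cat(sprintf("Energy context: RT = %.4f kcal/mol (T = %.2f K)\n",
              x$RT, x$temperature_K))
  invisible(x)
}

#' Parameters of a modulatory compound in the two-state model
#'
#' @param name compound label.
#' @param K_R equilibrium dissociation constant in the resting receptor
#'   (molar, > 0).
#' @param c gating efficacy: ratio of the dissociation constants in the
#'   active and resting receptor (> 0). `c < 1` means the compound
#'   stabilizes the active state (potentiator); `c > 1` an inhibitor.
#' @param N imposed number of binding sites (positive integer; by convention
#'   2 for the alpha7-nicotinic PAMs, 4 for propofol).
#' @return A validated list of class `modulator_params`.
#' @examples
#' modulator_params("NS-1738", K_R = 5e-6, c = 0.561, N = 2)
#' @export
modulator_params <- function(name, K_R, c, N = 2L) {
  if (!is.numeric(K_R) || length(K_R) != 1L || !is.finite(K_R) || K_R <= 0) {
    stop("'K_R' must be a single positive number (molar)", call. = FALSE)
  }
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0) {
    stop("'c' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N)) {
    stop("'N' must be a positive integer", call. = FALSE)
  }
  structure(
    list(name = as.character(name), K_R = K_R, c = c, N = as.integer(N)),
    class = "modulator_params"
  )
}

#' @export
print.modulator_params <- function(x, ...) {
  cat(sprintf("%s: K_R = %.3g M, c = %.4g, N = %d (%s)\n",
              x$name, x$K_R, x$c, x$N,
              if (x$c < 1) "active-state stabilizer" else
                if (x$c > 1) "inhibitor" else "neutral"))
  invisible(x)
}

#' Clamp probabilities away from 0 and 1
#'
#' Measured activation probabilities at the anchors (exactly 0 or 1) would
#' produce infinities in the log/ratio arithmetic of the model; they are
#' replaced by `eps` / `1 - eps`. Values strictly inside (0, 1) are valid
#' data and pass through unchanged; values outside \[0, 1\] are a
#' measurement error and are rejected.
#'
#' @param p numeric vector of probabilities in \[0, 1\].
#' @param eps boundary replacement margin (default 1e-6).
#' @return `p` with boundary values moved to `eps` / `1 - eps`.
#' @export
clamp_probability <- function(p, eps = 1e-6) {
  if (!is.numeric(p)) stop("'p' must be numeric", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  p[p == 0] <- eps
  p[p == 1] <- 1 - eps
  p
}

.odds_resting <- function(p_background, eps) {
  p <- clamp_probability(p_background, eps)
  (1 - p) / p
}

#' State function of the two-state cyclic co-agonist model
#'
#' Open probability in the presence of a modulator at concentration `conc`,
#' given the background open probability and the compound's resting-state
#' affinity `K_R`, efficacy `c` and site count `N`:
#' \deqn{P_A = \frac{1}{1 + \frac{1-p_{bg}}{p_{bg}}
#'   \left[\frac{1 + L/K_R}{1 + L/(K_R c)}\right]^N}}
#' The result increases with concentration when `c < 1`, decreases when
#' `c > 1`, and equals the background when `c = 1` or `conc = 0`.
#'
#' @param p_background open probability without the compound (in (0, 1)).
#' @param concentration applied concentration (molar, >= 0); vectorized.
#' @param params a [modulator_params()] object.
#' @param eps clamping margin for `p_background`.
#' @return Open probability with the compound bound, strictly in (0, 1).
#' @examples
#' ns <- modulator_params("NS-1738", K_R = 5e-6, c = 0.1, N = 2)
#' state_function(0.05, 1000 * ns$K_R, ns)
#' @seealso [saturating_state_function()] for the infinite-concentration
#'   limit used in all single-concentration analyses.
#' @export
state_function <- function(p_background, concentration, params, eps = 1e-6) {
  stopifnot(inherits(params, "modulator_params"))
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    stop("'concentration' must be finite and >= 0", call. = FALSE)
  }
  odds <- .odds_resting(p_background, eps)
  x <- concentration / params$K_R
  ratio <- (1 + x) / (1 + x / params$c)
  1 / (1 + odds * ratio^params$N)
}

#' Saturating-limit state function
#'
#' Limit of [state_function()] as concentration goes to infinity, where the
#' occupancy ratio collapses to `c^N`. All analyses at a near-saturating
#' concentration (>= 1000 x K_R) use this form.
#'
#' @param p_background open probability without the compound.
#' @param c gating efficacy (> 0); vectorized.
#' @param N imposed number of binding sites.
#' @param eps clamping margin.
#' @return Open probability at saturation, strictly in (0, 1).
#' @examples
#' saturating_state_function(0.05, c = 0.1, N = 2)  # 0.8403
#' @export
saturating_state_function <- function(p_background, c, N = 2L, eps = 1e-6) {
  if (any(!is.finite(c)) || any(c <= 0)) {
    stop("'c' must be finite and > 0", call. = FALSE)
  }
  odds <- .odds_resting(p_background, eps)
  1 / (1 + odds * c^N)
}

#' Gating efficacy from a background/modulated activation pair
#'
#' Inverts the saturating state function: given the open probability before
#' and during application of a saturating concentration of a compound with
#' `N` imposed binding sites,
#' \deqn{c = \left[\frac{1/p_{mod} - 1}{(1-p_{bg})/p_{bg}}\right]^{1/N}.}
#' The caller asserts that the compound was applied at a saturating
#' concentration; `c` estimated at sub-saturating concentrations is biased
#' toward 1.
#'
#' @param p_background open probability before/without the compound.
#' @param p_modulated open probability with the compound; same length as
#'   `p_background` or length 1.
#' @param N imposed number of binding sites.
#' @param eps clamping margin.
#' @return The gating efficacy `c` (> 0). Values < 1 indicate active-state
#'   stabilization; values > 1 indicate inhibition.
#' @examples
#' efficacy_from_activation(0.08, 0.10, N = 2)  # ~0.885
#' @export
efficacy_from_activation <- function(p_background, p_modulated, N = 2L,
                                     eps = 1e-6) {
  if (!is.numeric(N) || any(N < 1) || any(N != round(N))) {
    stop("'N' must be a positive integer", call. = FALSE)
  }
  odds_bg <- .odds_resting(p_background, eps)
  p_mod <- clamp_probability(p_modulated, eps)
  ((1 / p_mod - 1) / odds_bg)^(1 / N)
}

#' Free energy of active-state stabilization
#'
#' Converts a gating efficacy into the total free energy a saturating
#' compound contributes toward the active state, `dG = N * RT * ln(c)`
#' (kcal/mol). Unlike `c`, `dG` is comparable across compounds with
#' different site counts. Negative values stabilize the active state.
#'
#' @param c gating efficacy (> 0); vectorized.
#' @param N imposed number of binding sites.
#' @param ctx an [energy_context()]; supplies RT.
#' @return Free energy change in kcal/mol.
#' @examples
#' free_energy(0.302, N = 4)  # -2.84 kcal/mol
#' free_energy(1, N = 2)      # 0: neutral compound
#' @export
free_energy <- function(c, N = 2L, ctx = energy_context()) {
  stopifnot(inherits(ctx, "energy_context"))
  if (any(!is.finite(c)) || any(c <= 0)) {
    stop("'c' must be finite and > 0", call. = FALSE)
  }
  N * ctx$RT * log(c)
}

#' Gating efficacy implied by a free energy
#'
#' Inverse of [free_energy()]: `c = exp(dG / (N * RT))`. Used by the
#' synthetic-data generator to construct ground-truth efficacies from target
#' stabilization energies.
#'
#' @param dG free energy change (kcal/mol); vectorized.
#' @param N imposed number of binding sites.
#' @param ctx an [energy_context()].
#' @return The efficacy `c`.
#' @export
efficacy_from_energy <- function(dG, N = 2L, ctx = energy_context()) {
  stopifnot(inherits(ctx, "energy_context"))
  exp(dG / (N * ctx$RT))
}

#' Fold-potentiation as a function of background activity
#'
#' Tabulates the apparent modulation (fold change of the open probability at
#' a saturating concentration) over a grid of background open probabilities.
#' For an active-state stabilizer (`c < 1`) the fold is strictly decreasing
#' in the background: the same compound looks much more potent on a quiet
#' receptor than on one already near its ceiling, which is why `c` (or `dG`)
#' rather than fold-potentiation is the comparable measure of efficacy.
#'
#' @param c gating efficacy.
#' @param N imposed number of binding sites.
#' @param p_background_grid numeric vector of background open probabilities
#'   in (0, 1).
#' @param eps clamping margin.
#' @return A data.frame with columns `p_background`, `p_modulated`, `fold`.
#' @examples
#' fold_potentiation_curve(0.1, 2, c(0.05, 0.2, 0.5, 0.9))
#' @export
fold_potentiation_curve <- function(c, N = 2L,
                                    p_background_grid = seq(0.01, 0.99,
                                                            by = 0.01),
                                    eps = 1e-6) {
  p_bg <- clamp_probability(p_background_grid, eps)
  p_mod <- saturating_state_function(p_bg, c = c, N = N, eps = eps)
  data.frame(
    p_background = p_bg,
    p_modulated = p_mod,
    fold = p_mod / p_bg
  )
}
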