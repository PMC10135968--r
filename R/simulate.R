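# Synthetic per-oocyte data generator. Emulates the statistical structure
# of the recordings the analysis assumes: cell-to-cell scatter in background
# and constitutive open probability, a ground-truth gating efficacy acting
# through the saturating state function, multiplicative measurement noise
# on probabilities, and protocol selection by constitutive activity.

#' Specification of a simulated receptor x compound group
#'
#' @param receptor,compound labels.
#' @param n_cells number of cells (>= 2).
#' @param p_background_mean,p_background_sd cell-to-cell distribution of
#'   the low-GABA background open probability (mean in (0, 1), sd >= 0).
#' @param p_constitutive_mean,p_constitutive_sd distribution of the
#'   constitutive open probability.
#' @param c_true ground-truth gating efficacy (> 0).
#' @param N imposed number of binding sites.
#' @param measurement_cv relative (multiplicative) measurement noise on
#'   probabilities; default 0.05.
#' @param seed integer seed; all randomness in [simulate_cells()] flows
#'   from it.
#' @return A validated list of class `sim_spec`.
#' @examples
#' sim_spec("alpha1beta2gamma2L", "NS-1738", 25, c_true = 0.561, seed = 7)
#' @export
sim_spec <- function(receptor, compound, n_cells,
                     p_background_mean = 0.05, p_background_sd = 0.03,
                     p_constitutive_mean = 0.005,
                     p_constitutive_sd = 0.002,
                     c_true, N = 2L, measurement_cv = 0.05, seed = 1L) {
  if (!is.numeric(n_cells) || n_cells < 2 || n_cells != round(n_cells)) {
    stop("'n_cells' must be an integer >= 2", call. = FALSE)
  }
  for (m in c(p_background_mean, p_constitutive_mean)) {
    if (!is.finite(m) || m <= 0 || m >= 1) {
      stop("probability means must lie in (0, 1)", call. = FALSE)
    }
  }
  for (s in c(p_background_sd, p_constitutive_sd, measurement_cv)) {
    if (!is.finite(s) || s < 0) {
      stop("sds and measurement_cv must be >= 0", call. = FALSE)
    }
  }
  if (!is.finite(c_true) || c_true <= 0) {
    stop("'c_true' must be finite and > 0", call. = FALSE)
  }
  if (!is.numeric(N) || N < 1 || N != round(N)) {
    stop("'N' must be a positive integer", call. = FALSE)
  }
  structure(
    list(receptor = as.character(receptor),
         compound = as.character(compound),
         n_cells = as.integer(n_cells),
         p_background_mean = p_background_mean,
         p_background_sd = p_background_sd,
         p_constitutive_mean = p_constitutive_mean,
         p_constitutive_sd = p_constitutive_sd,
         c_true = c_true, N = as.integer(N),
         measurement_cv = measurement_cv, seed = as.integer(seed)),
    class = "sim_spec"
  )
}

# Truncated-normal draws by rejection; zero-sd collapses to the (clamped)
# mean. A cap on rejection rounds guards against degenerate windows.
.rtruncnorm <- function(n, mean, sd, lower, upper, max_rounds = 10000L) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  out <- numeric(0)
  for (i in seq_len(max_rounds)) {
    draw <- stats::rnorm(n - length(out), mean, sd)
    out <- c(out, draw[draw > lower & draw < upper])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop("truncated-normal rejection sampling failed to converge",
       call. = FALSE)
}

#' Simulate per-cell activation profiles
#'
#' For each cell: draw the constitutive and background open probabilities
#' from truncated normal distributions (windows (1e-4, 0.95) and
#' (0.005, 0.95)), select the protocol from the constitutive activity,
#' compute the modulated probability through the saturating state function
#' with the ground-truth efficacy, then apply multiplicative measurement
#' noise (`Normal(1, cv)`) to every measured probability and clamp to
#' (0, 1). Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [sim_spec()].
#' @return A [cell_profiles()] table with `spec$n_cells` rows.
#' @examples
#' profiles <- simulate_cells(sim_spec("wt", "NS-1738", 10, c_true = 0.561,
#'                                     seed = 3))
#' @export
simulate_cells <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells
  p_const <- .rtruncnorm(n, spec$p_constitutive_mean,
                         spec$p_constitutive_sd, 1e-4, 0.95)
  p_gaba <- .rtruncnorm(n, spec$p_background_mean,
                        spec$p_background_sd, 0.005, 0.95)
  noise <- function(k) stats::rnorm(k, 1, spec$measurement_cv)
  p_const_meas <- clamp_probability(pmin(pmax(p_const * noise(n), 0), 1))
  protocol_direct <- select_protocol(p_const_meas) == "direct_activation"
  bg_true <- ifelse(protocol_direct, p_const, p_gaba)
  p_mod_true <- saturating_state_function(bg_true, c = spec$c_true,
                                          N = spec$N)
  p_bg_meas <- clamp_probability(pmin(pmax(p_gaba * noise(n), 0), 1))
  p_mod_meas <- clamp_probability(pmin(pmax(p_mod_true * noise(n), 0), 1))
  # direct-activation cells have no low-GABA measurement: their background
  # column carries the measured constitutive probability
  p_bg_col <- ifelse(protocol_direct, p_const_meas, p_bg_meas)
  cell_profiles(
    cell_id = sprintf("%s_%s_c%03d", spec$receptor, spec$compound,
                      seq_len(n)),
    receptor = spec$receptor, compound = spec$compound,
    p_constitutive = p_const_meas,
    p_background = p_bg_col,
    p_modulated = p_mod_meas
  )
}

#' Simulate raw amplitude records for a group
#'
#' Maps the probabilities of [simulate_cells()] back to currents by the
#' inverse of the anchor normalization (`amplitude = zero + p * (full -
#' zero)`), adding optional Normal current noise, and emits one record per
#' cell and condition, including the per-cell picrotoxin and
#' GABA + propofol anchor records. Running the result back through
#' [profiles_from_amplitudes()] recovers the profiles up to the amplitude
#' noise.
#'
#' @param spec a [sim_spec()].
#' @param full_anchor,zero_anchor anchor currents (nA, distinct).
#' @param amplitude_sd SD of additive Normal current noise (nA, default 0).
#' @return A data.frame of amplitude records (columns `cell_id`,
#'   `receptor`, `compound`, `condition`, `amplitude_nA`).
#' @export
simulate_amplitudes <- function(spec, full_anchor = -4000,
                                zero_anchor = -50, amplitude_sd = 0) {
  span <- full_anchor - zero_anchor
  if (abs(span) <= 1e-12 * max(1, abs(full_anchor), abs(zero_anchor))) {
    stop("degenerate anchors: zero and full anchors coincide",
         call. = FALSE)
  }
  profiles <- simulate_cells(spec)
  to_amp <- function(p) zero_anchor + p * span
  conditions <- c(.ZERO_CONDITION, .FULL_CONDITION, "constitutive",
                  "low_GABA", "compound")
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    amps <- c(zero_anchor, full_anchor,
              to_amp(profiles$p_constitutive[i]),
              to_amp(profiles$p_background[i]),
              to_amp(profiles$p_modulated[i]))
    data.frame(cell_id = profiles$cell_id[i],
               receptor = profiles$receptor[i],
               compound = profiles$compound[i],
               condition = conditions, amplitude_nA = amps,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (amplitude_sd > 0) {
    out$amplitude_nA <- out$amplitude_nA +
      stats::rnorm(nrow(out), 0, amplitude_sd)
  }
  rownames(out) <- NULL
  out
}

#' Simulate a full study and run the analysis pipeline on it
#'
#' Simulates every group in `specs`, concatenates the per-cell profiles,
#' and summarizes them with [efficacy_summary()] into a group table
#' (modulation, c and dG as mean +/- SD with n). The summary's energy
#' columns feed directly into [mutant_cycle_report()].
#'
#' @param specs a list of [sim_spec()] objects (non-empty). Per-group seeds
#'   are used as given; supply distinct seeds for independent groups.
#' @param ctx an [energy_context()].
#' @return A list of class `sim_study`: `profiles` (all cells), `summary`
#'   (group table) and `specs`.
#' @examples
#' wt <- sim_spec("wt", "NS-1738", 10, c_true = 0.561, seed = 1)
#' mt <- sim_spec("mut", "NS-1738", 5, c_true = 2.8, seed = 2,
#'                p_constitutive_mean = 0.25, p_constitutive_sd = 0.05)
#' study <- simulate_study(list(wt, mt))
#' study$summary
#' @export
simulate_study <- function(specs, ctx = energy_context()) {
  if (!length(specs)) stop("'specs' must be non-empty", call. = FALSE)
  if (!all(vapply(specs, inherits, logical(1), "sim_spec"))) {
    stop("'specs' must be a list of sim_spec objects", call. = FALSE)
  }
  profiles <- do.call(rbind, lapply(specs, simulate_cells))
  site_counts <- vapply(specs, `[[`, integer(1), "N")
  names(site_counts) <- vapply(specs, `[[`, character(1), "compound")
  site_counts <- site_counts[!duplicated(names(site_counts))]
  summary <- efficacy_summary(profiles, site_counts = site_counts,
                              ctx = ctx)$summary
  structure(list(profiles = profiles, summary = summary, specs = specs),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("Simulated study: %d groups, %d cells\n",
              length(x$specs), nrow(x$profiles)))
  print(x$summary)
  invisible(x)
}
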