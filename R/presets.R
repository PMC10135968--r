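# Bundled reference data: group summaries (mean +/- SD, n) of modulation,
# gating efficacy c and stabilization energy dG for the alpha1beta2gamma2L
# GABA-A receptor and a panel of intersubunit-interface mutants, for the
# alpha7-nicotinic PAMs NS-1738 and PAM-2 ("pam" set), the anesthetics
# propofol/etomidate and the neurosteroid 3a5bP on the gamma2L(L246N)
# mutant ("anesthetic" set), and 3a5bP across interface mutants
# ("steroid" set). Subunit names are ASCII (alpha1beta2gamma2L etc.).

#' Reference group summaries bundled with the package
#'
#' Per receptor x compound: modulation percent, efficacy `c` and energy
#' `dG` (each mean +/- SD), cell count `n`, imposed site count `N`, whether
#' the receptor was analyzed by direct activation (`constitutive == 1`),
#' and — where available — the constitutive and background open-probability
#' statistics used by the simulation presets.
#'
#' @param set one of `"pam"`, `"anesthetic"`, `"steroid"`, or `"all"`.
#' @return A data.frame; its (`receptor`, `compound`, `mean_dG`, `sd_dG`,
#'   `n`) columns form a valid [group_summary()] table.
#' @examples
#' head(reference_summaries("pam"))
#' @export
reference_summaries <- function(set = c("pam", "anesthetic", "steroid",
                                        "all")) {
  set <- match.arg(set)
  path <- system.file("extdata", "reference_group_summaries.csv",
                      package = "gabamod", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  names(tab)[names(tab) == "dG_mean"] <- "mean_dG"
  names(tab)[names(tab) == "dG_sd"] <- "sd_dG"
  if (set != "all") tab <- tab[tab$set == set, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Simulation preset for a reference receptor x compound group
#'
#' Builds a [sim_spec()] whose ground truth mirrors a bundled reference
#' group: `c_true` is derived from the group's mean stabilization energy
#' (`c_true = exp(mean_dG / (N RT))`, so the simulated per-cell dG mean
#' targets the reference value), `n_cells` equals the reference n, and the
#' background/constitutive distributions use the recorded statistics where
#' available (defaults: background 0.05 +/- 0.03, constitutive
#' 0.005 +/- 0.002 for receptors without appreciable spontaneous activity).
#'
#' @param receptor,compound labels as in [reference_summaries()].
#' @param set which reference set to search.
#' @param seed seed stored in the spec.
#' @param measurement_cv relative measurement noise (default 0.05).
#' @param ctx an [energy_context()].
#' @return A `sim_spec` object.
#' @examples
#' sim_preset("alpha1beta2gamma2L", "NS-1738", seed = 1)
#' @export
sim_preset <- function(receptor, compound, set = "all", seed = 1L,
                       measurement_cv = 0.05, ctx = energy_context()) {
  tab <- reference_summaries(set)
  row <- tab[tab$receptor == receptor & tab$compound == compound, ,
             drop = FALSE]
  if (nrow(row) == 0L) {
    stop(sprintf("no reference group for receptor '%s', compound '%s'",
                 receptor, compound), call. = FALSE)
  }
  row <- row[1L, ]
  c_true <- efficacy_from_energy(row$mean_dG, N = row$N, ctx = ctx)
  if (row$constitutive == 1) {
    p_const_mean <- if (is.na(row$p_const_mean)) 0.1 else row$p_const_mean
    p_const_sd <- if (is.na(row$p_const_sd)) 0.05 else row$p_const_sd
  } else {
    p_const_mean <- 0.005
    p_const_sd <- 0.002
  }
  p_bg_mean <- if (is.na(row$p_bg_mean)) 0.05 else row$p_bg_mean
  p_bg_sd <- if (is.na(row$p_bg_sd)) 0.03 else row$p_bg_sd
  sim_spec(receptor = receptor, compound = compound, n_cells = row$n,
           p_background_mean = p_bg_mean, p_background_sd = p_bg_sd,
           p_constitutive_mean = p_const_mean,
           p_constitutive_sd = p_const_sd,
           c_true = c_true, N = row$N,
           measurement_cv = measurement_cv, seed = seed)
}
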