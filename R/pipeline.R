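# Pipeline stages tying the modules together: configuration, per-cell
# efficacy estimation with group summaries, mutant-cycle reporting, and
# reproducible file output with manifests.

#' Analysis run configuration
#'
#' Collects the conventions every stage shares: the thermal energy, the
#' confidence-interval quantile, the probability clamping margin, the
#' constitutive-activity thresholds (audit band lower edge, protocol switch
#' point), the per-compound imposed site counts and the seed.
#'
#' @param ctx an [energy_context()].
#' @param z_quantile normal quantile for confidence intervals (default
#'   1.96).
#' @param clamp_epsilon probability clamping margin.
#' @param constitutive_thresholds ordered pair: audit-band lower edge and
#'   direct-activation switch point (default `c(0.01, 0.02)`).
#' @param site_counts named numeric vector mapping compound to imposed
#'   site count N.
#' @param seed integer seed for stochastic stages.
#' @return A validated list of class `run_config`.
#' @examples
#' run_config()
#' @export
run_config <- function(ctx = energy_context(), z_quantile = 1.96,
                       clamp_epsilon = 1e-6,
                       constitutive_thresholds = c(0.01, 0.02),
                       site_counts = c("NS-1738" = 2, "PAM-2" = 2,
                                       "propofol" = 4, "etomidate" = 2,
                                       "3a5bP" = 2),
                       seed = 1L) {
  stopifnot(inherits(ctx, "energy_context"))
  if (length(constitutive_thresholds) != 2L ||
      constitutive_thresholds[1] > constitutive_thresholds[2]) {
    stop("'constitutive_thresholds' must be an ordered pair", call. = FALSE)
  }
  if (!is.numeric(z_quantile) || z_quantile <= 0) {
    stop("'z_quantile' must be > 0", call. = FALSE)
  }
  if (is.null(names(site_counts)) || any(names(site_counts) == "") ||
      any(site_counts < 1)) {
    stop("'site_counts' must be a named vector of site counts >= 1",
         call. = FALSE)
  }
  structure(
    list(ctx = ctx, z_quantile = z_quantile,
         clamp_epsilon = clamp_epsilon,
         constitutive_thresholds = constitutive_thresholds,
         site_counts = site_counts, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys: `temperature_K` or `RT`, `z_quantile`, `clamp_epsilon`,
#' `constitutive_thresholds` (2-vector), `site_counts` (map), `seed`.
#' Missing keys fall back to the [run_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ctx <- if (!is.null(raw$RT)) {
    energy_context(temperature_K = raw$temperature_K %||%
                     .DEFAULT_TEMPERATURE_K, RT = raw$RT)
  } else if (!is.null(raw$temperature_K)) {
    energy_context(temperature_K = raw$temperature_K)
  } else {
    energy_context()
  }
  defaults <- run_config()
  run_config(
    ctx = ctx,
    z_quantile = raw$z_quantile %||% defaults$z_quantile,
    clamp_epsilon = raw$clamp_epsilon %||% defaults$clamp_epsilon,
    constitutive_thresholds = unlist(raw$constitutive_thresholds) %||%
      defaults$constitutive_thresholds,
    site_counts = if (!is.null(raw$site_counts))
      unlist(raw$site_counts) else defaults$site_counts,
    seed = raw$seed %||% defaults$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- schema validation -----------------------------------------------------

#' Validate a per-cell profile table before analysis
#'
#' Rejects missing columns, probabilities outside \[0, 1\] and empty
#' tables, listing the offending rows.
#'
#' @param profiles candidate profile table.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_profiles <- function(profiles) {
  .check_profiles(profiles)
  if (nrow(profiles) == 0L) {
    stop("profile table is empty", call. = FALSE)
  }
  bad <- which(
    !is.finite(profiles$p_constitutive) | profiles$p_constitutive < 0 |
      profiles$p_constitutive > 1 |
      !is.finite(profiles$p_background) | profiles$p_background < 0 |
      profiles$p_background > 1 |
      !is.finite(profiles$p_modulated) | profiles$p_modulated < 0 |
      profiles$p_modulated > 1
  )
  if (length(bad)) {
    stop("probabilities outside [0, 1] in row(s): ",
         paste(utils::head(bad, 20), collapse = ", "), call. = FALSE)
  }
  invisible(profiles)
}

# ---- per-cell efficacy pipeline --------------------------------------------

#' Per-cell efficacy estimates and group summaries
#'
#' For every cell: background per protocol, modulation percent, gating
#' efficacy `c` (saturating-limit inversion with the compound's site
#' count) and stabilization energy `dG`. Groups by receptor x compound and
#' reports mean +/- SD and n of each quantity — the group table whose
#' energy columns feed [mutant_cycle_report()]. Per-cell values are always
#' computed first and then averaged; `c` and `dG` are never derived from
#' group-mean probabilities.
#'
#' @param profiles a [cell_profiles()] table.
#' @param site_counts named vector mapping compound to N; compounds absent
#'   from the map are an error.
#' @param ctx an [energy_context()].
#' @param eps probability clamping margin.
#' @return A list of class `efficacy_result`: `cells` (per-cell table with
#'   `modulation`, `c`, `dG` columns) and `summary` (group table with
#'   columns `receptor`, `compound`, `n`, `modulation_mean`,
#'   `modulation_sd`, `c_mean`, `c_sd`, `mean_dG`, `sd_dG`, `n_flagged`).
#' @export
efficacy_summary <- function(profiles,
                             site_counts = c("NS-1738" = 2, "PAM-2" = 2,
                                             "propofol" = 4,
                                             "etomidate" = 2, "3a5bP" = 2),
                             ctx = energy_context(), eps = 1e-6) {
  validate_profiles(profiles)
  unknown <- setdiff(unique(profiles$compound), names(site_counts))
  if (length(unknown)) {
    stop("no imposed site count for compound(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cells <- as.data.frame(profiles)
  N <- unname(site_counts[cells$compound])
  bg <- background_pa(profiles)
  cells$modulation <- modulation_percent(profiles)
  cells$c <- efficacy_from_activation(bg, cells$p_modulated, N = N,
                                      eps = eps)
  cells$dG <- free_energy(cells$c, N = N, ctx = ctx)
  key <- interaction(cells$receptor, cells$compound, drop = TRUE)
  groups <- lapply(split(cells, key), function(g) {
    data.frame(
      receptor = g$receptor[1], compound = g$compound[1],
      n = nrow(g),
      modulation_mean = mean(g$modulation),
      modulation_sd = stats::sd(g$modulation),
      c_mean = mean(g$c), c_sd = stats::sd(g$c),
      mean_dG = mean(g$dG), sd_dG = stats::sd(g$dG),
      n_flagged = sum(g$band_flag),
      stringsAsFactors = FALSE
    )
  })
  summary <- do.call(rbind, groups)
  rownames(summary) <- NULL
  structure(list(cells = cells, summary = summary),
            class = "efficacy_result")
}

#' @export
print.efficacy_result <- function(x, ...) {
  cat(sprintf("Efficacy estimates for %d cells in %d groups\n",
              nrow(x$cells), nrow(x$summary)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %-22s %-10s n=%2d  mod %5.0f%%  c %.3f +/- %.3f  dG %6.2f +/- %.2f\n",
      s$receptor[i], s$compound[i], s$n[i], s$modulation_mean[i],
      s$c_mean[i], s$c_sd[i], s$mean_dG[i], s$sd_dG[i]))
  }
  if (any(x$summary$n_flagged > 0)) {
    cat(sprintf("  note: %d cell(s) in the constitutive audit band\n",
                sum(x$summary$n_flagged)))
  }
  invisible(x)
}

# ---- file-level pipeline stages --------------------------------------------

# 32-bit FNV-1a over the serialized object; cheap content fingerprint for
# manifests (not cryptographic).
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, ascii = TRUE)[-(1:14)])
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

.write_manifest <- function(path, config, extra = list()) {
  manifest <- c(list(
    package = "gabamod",
    version = as.character(utils::packageVersion("gabamod")),
    seed = config$seed,
    RT = config$ctx$RT,
    temperature_K = config$ctx$temperature_K,
    z_quantile = config$z_quantile,
    clamp_epsilon = config$clamp_epsilon,
    constitutive_thresholds = config$constitutive_thresholds,
    site_counts = as.list(config$site_counts),
    config_hash = .config_hash(config)
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Atomic CSV write: stage into a temp file in the target directory, then
# rename, so a failed run leaves no partial output.
.write_csv_atomic <- function(tab, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  utils::write.csv(tab, tmp, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  file.rename(tmp, path)
  invisible(path)
}

#' Pipeline stage: simulate a study and write its tables
#'
#' Validates the specs, simulates all groups, and writes
#' `cells.csv` (per-cell profiles), `summary.csv` (group table) and
#' `manifest.json` into `out_dir`. Output is atomic: nothing is written if
#' any spec is invalid.
#'
#' @param config a [run_config()].
#' @param specs list of [sim_spec()] objects.
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
run_simulate <- function(config, specs, out_dir) {
  stopifnot(inherits(config, "run_config"))
  study <- simulate_study(specs, ctx = config$ctx)  # validates specs
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(cells = file.path(out_dir, "cells.csv"),
             summary = file.path(out_dir, "summary.csv"),
             manifest = file.path(out_dir, "manifest.json"))
  .write_csv_atomic(as.data.frame(study$profiles), files["cells"])
  .write_csv_atomic(study$summary, files["summary"])
  .write_manifest(files["manifest"], config,
                  extra = list(stage = "simulate",
                               n_groups = length(specs),
                               n_cells = nrow(study$profiles)))
  invisible(files)
}

#' Pipeline stage: per-cell efficacy report from a profile table
#'
#' Reads (or accepts) a per-cell profile table, validates the schema, and
#' writes the group summary table plus manifest. The written summary is
#' column-for-column comparable to the bundled reference tables:
#' modulation percent, `c` and `dG` each as mean +/- SD, with n.
#'
#' @param config a [run_config()].
#' @param profiles a `cell_profiles` table or path to a profile CSV.
#' @param out_dir output directory.
#' @return The `efficacy_result`, invisibly; files `efficacy.csv` and
#'   `manifest.json` are written.
#' @export
run_efficacy <- function(config, profiles, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(profiles)) {
    profiles <- read_profile_table(
      profiles, band = config$constitutive_thresholds)
  }
  res <- efficacy_summary(profiles, site_counts = config$site_counts,
                          ctx = config$ctx, eps = config$clamp_epsilon)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_csv_atomic(res$summary, file.path(out_dir, "efficacy.csv"))
  .write_manifest(file.path(out_dir, "manifest.json"), config,
                  extra = list(stage = "efficacy",
                               n_cells = nrow(res$cells),
                               n_flagged = sum(res$cells$band_flag)))
  invisible(res)
}

#' Pipeline stage: mutant-cycle report from a group-summary table
#'
#' @param config a [run_config()].
#' @param summaries a group-summary table or path to its CSV.
#' @param compound compound to analyze.
#' @param wildtype wild-type receptor label.
#' @param mutants mutant receptor labels (default: all others).
#' @param out_dir output directory; `mutant_cycle.csv`, a human-readable
#'   `mutant_cycle.txt` and `manifest.json` are written.
#' @return The `mutant_cycle_report`, invisibly.
#' @export
run_mutant_cycle <- function(config, summaries, compound, wildtype,
                             mutants = NULL, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(summaries)) summaries <- read_group_summaries(summaries)
  report <- mutant_cycle_report(summaries, compound = compound,
                                wildtype = wildtype, mutants = mutants,
                                z = config$z_quantile)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_csv_atomic(report$table, file.path(out_dir, "mutant_cycle.csv"))
  txt <- file.path(out_dir, "mutant_cycle.txt")
  con <- file(txt, "w", encoding = "UTF-8")
  sink(con); print(report); sink(); close(con)
  .write_manifest(file.path(out_dir, "manifest.json"), config,
                  extra = list(stage = "mutant_cycle", compound = compound,
                               wildtype = wildtype,
                               additive = report$verdict$additive))
  invisible(report)
}
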