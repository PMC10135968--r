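# Mutant-cycle additivity analysis on group delta-G summaries.
#
# Each group is summarized as the mean +/- SD of per-cell stabilization
# energies (never from group-mean open probabilities: the c -> dG transform
# is nonlinear). ddG = mutant - wild type; with independent binding sites
# the mutation-induced losses should satisfy dG_wt = -sum(ddG_i).

#' Construct a group summary of stabilization energies
#'
#' One row per receptor x compound: mean, SD and n of per-cell dG values
#' (kcal/mol).
#'
#' @param receptor,compound labels (recycled).
#' @param mean_dG group mean dG (kcal/mol).
#' @param sd_dG group SD (>= 0).
#' @param n number of cells (>= 2).
#' @return A data.frame of class `group_summary`.
#' @examples
#' group_summary("alpha1beta2gamma2L", "NS-1738", -0.70, 0.23, 25)
#' @export
group_summary <- function(receptor, compound, mean_dG, sd_dG, n) {
  if (any(!is.finite(mean_dG))) stop("'mean_dG' must be finite", call. = FALSE)
  if (any(!is.finite(sd_dG)) || any(sd_dG < 0)) {
    stop("'sd_dG' must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(n)) || any(n < 2) || any(n != round(n))) {
    stop("'n' must be an integer >= 2", call. = FALSE)
  }
  out <- data.frame(
    receptor = as.character(receptor), compound = as.character(compound),
    mean_dG = mean_dG, sd_dG = sd_dG, n = as.integer(n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("group_summary", "data.frame")
  out
}

.as_summary_row <- function(x, what) {
  need <- c("receptor", "compound", "mean_dG", "sd_dG", "n")
  if (is.list(x) && !is.data.frame(x)) x <- as.data.frame(x)
  if (!is.data.frame(x) || nrow(x) != 1L || !all(need %in% names(x))) {
    stop(sprintf("'%s' must be a single group-summary row", what),
         call. = FALSE)
  }
  if (x$n < 2) stop(sprintf("'%s': n must be >= 2", what), call. = FALSE)
  x
}

#' Mutation-induced change in stabilization energy (ddG)
#'
#' `ddG = mean_dG(mutant) - mean_dG(wild type)`, with standard error
#' propagated from the two group summaries,
#' `se = sqrt(sd_wt^2/n_wt + sd_mut^2/n_mut)`, and a normal-approximation
#' confidence interval `ddG +/- z * se`. A potentiation-reducing mutation
#' (wild-type dG < 0, mutant dG larger) gives ddG > 0.
#'
#' @param mutant,wildtype single [group_summary()] rows for the same
#'   compound.
#' @param z normal quantile for the confidence interval (default 1.96 for
#'   95%).
#' @return An object of class `coupling_result`: list with `compound`,
#'   `components` (labels), `ddG`, `se`, `ci_low`, `ci_high`, `z` and the
#'   variance split `var_mutant` / `var_wildtype` used for optional
#'   covariance-aware summation.
#' @examples
#' wt <- group_summary("WT", "NS-1738", -0.70, 0.23, 25)
#' mt <- group_summary("beta2(F289T)", "NS-1738", 1.22, 0.47, 5)
#' ddg(mt, wt)  # 1.92 [1.50, 2.34]
#' @export
ddg <- function(mutant, wildtype, z = 1.96) {
  mutant <- .as_summary_row(mutant, "mutant")
  wildtype <- .as_summary_row(wildtype, "wildtype")
  if (mutant$compound != wildtype$compound) {
    stop("mutant and wildtype summaries are for different compounds",
         call. = FALSE)
  }
  var_mut <- mutant$sd_dG^2 / mutant$n
  var_wt <- wildtype$sd_dG^2 / wildtype$n
  est <- mutant$mean_dG - wildtype$mean_dG
  se <- sqrt(var_mut + var_wt)
  structure(
    list(compound = mutant$compound,
         components = c(mutant = mutant$receptor,
                        wildtype = wildtype$receptor),
         ddG = est, se = se,
         ci_low = est - z * se, ci_high = est + z * se,
         z = z, var_mutant = var_mut, var_wildtype = var_wt),
    class = "coupling_result"
  )
}

#' @export
print.coupling_result <- function(x, ...) {
  lab <- if (length(x$components) > 2L) {
    paste("sum over", paste(unique(x$components[names(x$components) ==
                                                  "mutant"]),
                            collapse = ", "))
  } else {
    paste(x$components, collapse = " - ")
  }
  cat(sprintf("%s (%s): ddG = %.2f [%.2f, %.2f] kcal/mol (se %.3f)\n",
              lab, x$compound, x$ddG, x$ci_low, x$ci_high, x$se))
  invisible(x)
}

#' Sum of ddG values across interfaces
#'
#' Adds the point estimates; by default the component variances are added
#' as if independent (each already contains the wild-type term), which is
#' the convention under which the propagated interval matches the per-pair
#' intervals. With `covariance_aware = TRUE` the shared wild-type group
#' enters the variance once as `k^2 * var_wt` (k components) instead of
#' k times, the correct treatment when all ddGs were formed against the
#' same wild-type mean.
#'
#' @param results list of `coupling_result` objects for the same compound.
#' @param covariance_aware account for the shared wild-type group (default
#'   `FALSE`).
#' @return A `coupling_result` for the sum (components concatenated).
#' @examples
#' wt <- group_summary("WT", "NS-1738", -0.70, 0.23, 25)
#' muts <- list(
#'   group_summary("beta2(F289T)", "NS-1738", 1.22, 0.47, 5),
#'   group_summary("alpha1(Y293C)", "NS-1738", 0.31, 0.14, 5),
#'   group_summary("gamma2L(F304C)", "NS-1738", 0.74, 0.29, 5)
#' )
#' additivity_sum(lapply(muts, ddg, wildtype = wt))  # 4.37 [3.85, 4.89]
#' @export
additivity_sum <- function(results, covariance_aware = FALSE) {
  if (!length(results)) stop("empty list of coupling results", call. = FALSE)
  if (!all(vapply(results, inherits, logical(1), "coupling_result"))) {
    stop("'results' must be a list of coupling_result objects",
         call. = FALSE)
  }
  compounds <- unique(vapply(results, `[[`, character(1), "compound"))
  if (length(compounds) != 1L) {
    stop("coupling results mix compounds: ",
         paste(compounds, collapse = ", "), call. = FALSE)
  }
  z <- results[[1]]$z
  est <- sum(vapply(results, `[[`, numeric(1), "ddG"))
  var_mut <- sum(vapply(results, `[[`, numeric(1), "var_mutant"))
  var_wt_each <- vapply(results, `[[`, numeric(1), "var_wildtype")
  variance <- if (covariance_aware) {
    var_mut + length(results)^2 * var_wt_each[1]
  } else {
    var_mut + sum(var_wt_each)
  }
  se <- sqrt(variance)
  structure(
    list(compound = compounds,
         components = unlist(lapply(results, `[[`, "components")),
         ddG = est, se = se,
         ci_low = est - z * se, ci_high = est + z * se,
         z = z, var_mutant = var_mut,
         var_wildtype = if (covariance_aware)
           length(results)^2 * var_wt_each[1] else sum(var_wt_each)),
    class = "coupling_result"
  )
}

#' Test energetic additivity against the wild-type energy
#'
#' Under additive, independent binding sites the mutation-induced losses
#' account for the whole wild-type stabilization: `dG_wt = -sum(ddG_i)`,
#' i.e. `-dG_wt` must fall inside the confidence interval of the summed
#' ddG. A sum whose interval excludes `-dG_wt` indicates coupling between
#' the sites.
#'
#' @param sum_result a `coupling_result` from [additivity_sum()].
#' @param wildtype the wild-type [group_summary()] row (same compound).
#' @return An object of class `additivity_verdict`: list with `compound`,
#'   `sum_ddG`, `ci_low`, `ci_high`, `neg_dG_wt` and logical `additive`.
#' @export
additivity_test <- function(sum_result, wildtype) {
  stopifnot(inherits(sum_result, "coupling_result"))
  wildtype <- .as_summary_row(wildtype, "wildtype")
  if (sum_result$compound != wildtype$compound) {
    stop("sum and wildtype summaries are for different compounds",
         call. = FALSE)
  }
  target <- -wildtype$mean_dG
  structure(
    list(compound = sum_result$compound,
         sum_ddG = sum_result$ddG,
         ci_low = sum_result$ci_low, ci_high = sum_result$ci_high,
         neg_dG_wt = target,
         additive = target >= sum_result$ci_low &
           target <= sum_result$ci_high),
    class = "additivity_verdict"
  )
}

#' @export
print.additivity_verdict <- function(x, ...) {
  cat(sprintf("Additivity test (%s):\n", x$compound))
  cat(sprintf("  sum of ddG = %.2f [%.2f, %.2f] kcal/mol\n",
              x$sum_ddG, x$ci_low, x$ci_high))
  cat(sprintf("  -dG(wild type) = %.2f kcal/mol\n", x$neg_dG_wt))
  cat(if (x$additive)
    "  -> consistent with additive, independent sites\n"
    else
      "  -> NOT additive: interval excludes -dG(wild type)\n")
  invisible(x)
}

#' Full mutant-cycle report for one compound
#'
#' Extracts the wild-type and mutant rows from a group-summary table,
#' computes every per-mutation ddG with its confidence interval, their sum,
#' and the additivity verdict.
#'
#' @param summaries a [group_summary()] table (several rows).
#' @param compound compound to analyze.
#' @param wildtype receptor label of the wild-type row.
#' @param mutants receptor labels of the mutant rows; default all non
#'   wild-type receptors present for the compound.
#' @param z normal quantile for confidence intervals.
#' @param covariance_aware passed to [additivity_sum()].
#' @return An object of class `mutant_cycle_report`: list with `table`
#'   (data.frame of ddG rows plus the sum), `sum` (`coupling_result`) and
#'   `verdict` (`additivity_verdict`).
#' @export
mutant_cycle_report <- function(summaries, compound, wildtype,
                                mutants = NULL, z = 1.96,
                                covariance_aware = FALSE) {
  need <- c("receptor", "compound", "mean_dG", "sd_dG", "n")
  missing <- setdiff(need, names(summaries))
  if (length(missing)) {
    stop("summary table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sub <- summaries[summaries$compound == compound, , drop = FALSE]
  wt <- sub[sub$receptor == wildtype, , drop = FALSE]
  if (nrow(wt) != 1L) {
    stop(sprintf("wild-type row '%s' for compound '%s' not found (or not unique)",
                 wildtype, compound), call. = FALSE)
  }
  if (is.null(mutants)) mutants <- setdiff(sub$receptor, wildtype)
  if (!length(mutants)) {
    stop("no mutant rows selected for the mutant cycle", call. = FALSE)
  }
  absent <- setdiff(mutants, sub$receptor)
  if (length(absent)) {
    stop("mutant row(s) not found: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  results <- lapply(mutants, function(r) {
    ddg(sub[sub$receptor == r, , drop = FALSE], wt, z = z)
  })
  total <- additivity_sum(results, covariance_aware = covariance_aware)
  verdict <- additivity_test(total, wt)
  tab <- data.frame(
    receptor = c(mutants, "sum"),
    ddG = c(vapply(results, `[[`, numeric(1), "ddG"), total$ddG),
    se = c(vapply(results, `[[`, numeric(1), "se"), total$se),
    ci_low = c(vapply(results, `[[`, numeric(1), "ci_low"), total$ci_low),
    ci_high = c(vapply(results, `[[`, numeric(1), "ci_high"), total$ci_high),
    stringsAsFactors = FALSE
  )
  structure(
    list(compound = compound, wildtype = wildtype, table = tab,
         results = results, sum = total, verdict = verdict),
    class = "mutant_cycle_report"
  )
}

#' @export
print.mutant_cycle_report <- function(x, ...) {
  cat(sprintf("Mutant cycle: %s, wild type %s\n", x$compound, x$wildtype))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-20s ddG %6.2f [%5.2f, %5.2f] kcal/mol\n",
                tab$receptor[i], tab$ddG[i], tab$ci_low[i], tab$ci_high[i]))
  }
  print(x$verdict)
  invisible(x)
}

#' Read a group-summary CSV
#'
#' Columns `receptor`, `compound`, `mean_dG`, `sd_dG`, `n`.
#'
#' @param path file path.
#' @return A validated `group_summary` data.frame.
#' @export
read_group_summaries <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("receptor", "compound", "mean_dG", "sd_dG", "n")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("summary table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  group_summary(tab$receptor, tab$compound, tab$mean_dG, tab$sd_dG, tab$n)
}
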