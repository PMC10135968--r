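# Quantification of substituted-cysteine modification-protection (SCAMP)
# experiments: a covalent label (pCMB) applied to an engineered cysteine
# shifts the low/high GABA response ratio; co-application of a ligand that
# occupies the site blunts the shift.

#' Fold change of the low/high GABA response ratio after labeling
#'
#' Each cell is characterized by the ratio of its response to a low versus a
#' saturating GABA concentration, measured before and after exposure to the
#' cysteine-modifying reagent. The ratio is scale-invariant in the raw
#' currents (a common gain on both responses cancels), so the fold change
#' `after / before` isolates the functional effect of labeling: 1 means no
#' modification effect.
#'
#' @param ratio_before low/high GABA response ratio before modification
#'   (> 0); vectorized.
#' @param ratio_after the same ratio after modification (> 0).
#' @return Fold change `ratio_after / ratio_before`.
#' @examples
#' ratio_fold_change(0.12, 0.57)  # unprotected: ~4.8-fold increase
#' ratio_fold_change(0.12, 0.23)  # protected: ~1.9-fold
#' @export
ratio_fold_change <- function(ratio_before, ratio_after) {
  if (any(!is.finite(ratio_before)) || any(ratio_before <= 0)) {
    stop("'ratio_before' must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(ratio_after)) || any(ratio_after <= 0)) {
    stop("'ratio_after' must be finite and > 0", call. = FALSE)
  }
  ratio_after / ratio_before
}

#' Compare labeling fold changes with and without a protecting ligand
#'
#' Welch two-sample comparison of per-cell fold changes between the
#' unprotected (reagent alone) and protected (reagent + ligand) groups.
#' Protection is flagged when the protected group's mean fold change is
#' significantly smaller than the control's (one-sided Welch test at level
#' `alpha`): the ligand occupying the site shields the cysteine from the
#' label.
#'
#' @param control_folds fold changes with the reagent alone (n >= 2).
#' @param protected_folds fold changes with reagent + protecting ligand
#'   (n >= 2).
#' @param alpha significance level for the protection flag (default 0.05).
#' @return An object of class `protection_index`: list with
#'   `mean_control`, `mean_protected`, `difference` (control - protected),
#'   `t`, `df`, `p_value` (one-sided, control > protected) and logical
#'   `protected`.
#' @examples
#' set.seed(1)
#' protection_index(rnorm(7, 5.0, 1.8), rnorm(7, 1.9, 0.4))
#' @export
protection_index <- function(control_folds, protected_folds, alpha = 0.05) {
  if (length(control_folds) < 2L || length(protected_folds) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  m_c <- mean(control_folds)
  m_p <- mean(protected_folds)
  ht <- tryCatch(
    stats::t.test(control_folds, protected_folds,
                  alternative = "greater", var.equal = FALSE),
    error = function(e) NULL
  )
  if (is.null(ht)) {
    # both groups essentially constant: decide on the means alone
    p_value <- if (m_c > m_p) 0 else 1
    t_stat <- if (m_c == m_p) 0 else sign(m_c - m_p) * Inf
    df <- length(control_folds) + length(protected_folds) - 2
  } else {
    p_value <- ht$p.value
    t_stat <- unname(ht$statistic)
    df <- unname(ht$parameter)
  }
  structure(
    list(mean_control = m_c, mean_protected = m_p,
         difference = m_c - m_p, t = t_stat, df = df,
         p_value = p_value, alpha = alpha,
         protected = is.finite(p_value) && p_value < alpha && m_p < m_c),
    class = "protection_index"
  )
}

#' @export
print.protection_index <- function(x, ...) {
  cat(sprintf(
    "Protection assay: mean fold %.2f (control) vs %.2f (protected)\n",
    x$mean_control, x$mean_protected))
  cat(sprintf("  Welch t = %.2f, df = %.1f, one-sided p = %.3g\n",
              x$t, x$df, x$p_value))
  cat(if (x$protected) "  -> protection detected\n" else
    "  -> no protection detected\n")
  invisible(x)
}

#' Read a protection-assay record table
#'
#' CSV with columns `cell_id`, `ratio_before`, `ratio_after`, `protectant`
#' (e.g. "none", "NS-1738", "PAM-2").
#'
#' @param path file path.
#' @return A validated data.frame.
#' @export
read_protection_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("cell_id", "ratio_before", "ratio_after", "protectant")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("protection table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(tab$ratio_before <= 0) || any(tab$ratio_after <= 0)) {
    stop("response ratios must be > 0", call. = FALSE)
  }
  tab
}

#' Summarize a protection experiment by protectant group
#'
#' Computes per-cell fold changes and compares every protected group against
#' the `"none"` control with [protection_index()].
#'
#' @param records table as from [read_protection_table()].
#' @param alpha significance level for the protection flags.
#' @return A list with `folds` (records plus a `fold` column) and
#'   `comparisons` (one `protection_index` per protectant).
#' @export
protection_summary <- function(records, alpha = 0.05) {
  records$fold <- ratio_fold_change(records$ratio_before,
                                    records$ratio_after)
  control <- records$fold[records$protectant == "none"]
  if (length(control) < 2L) {
    stop("need >= 2 control ('none') cells", call. = FALSE)
  }
  groups <- setdiff(unique(records$protectant), "none")
  comparisons <- lapply(groups, function(g) {
    protection_index(control, records$fold[records$protectant == g],
                     alpha = alpha)
  })
  names(comparisons) <- groups
  list(folds = records, comparisons = comparisons)
}
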