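# Open-probability normalization of oocyte currents.
#
# Convention: per cell, 200 uM picrotoxin defines the zero-activation anchor
# (all channels blocked, P_A = 0) and 1 mM GABA + 50 uM propofol the
# full-activation anchor (P_A = 1). Amplitudes are signed; the affine anchor
# mapping handles either polarity (inward currents negative).

#' Map a current amplitude to an open probability
#'
#' Linear interpolation between a cell's zero-activation anchor (picrotoxin,
#' P_A = 0) and full-activation anchor (GABA + propofol, P_A = 1), clamped
#' to \[0, 1\]. The mapping is affine-invariant: adding a constant offset to
#' all three currents, or scaling them by a common gain, leaves the result
#' unchanged.
#'
#' @param amplitude measured current (nA, signed); vectorized.
#' @param zero_anchor current with all receptors blocked.
#' @param full_anchor current with all receptors activated.
#' @return Open probability in \[0, 1\].
#' @examples
#' normalize_amplitude(-2525, zero_anchor = -50, full_anchor = -5000)
#' @export
normalize_amplitude <- function(amplitude, zero_anchor, full_anchor) {
  span <- full_anchor - zero_anchor
  tol <- 1e-12 * max(1, abs(full_anchor), abs(zero_anchor))
  if (any(abs(span) <= tol)) {
    stop("degenerate anchors: zero and full anchors coincide", call. = FALSE)
  }
  p <- (amplitude - zero_anchor) / span
  pmin(pmax(p, 0), 1)
}

#' Choose the measurement protocol from constitutive activity
#'
#' Receptors with appreciable spontaneous opening (constitutive open
#' probability strictly above 0.02) are probed by direct activation: the
#' modulator is applied without GABA and compared against the holding
#' current. Quiet receptors are probed by potentiation of a low-GABA
#' response. The boundary value 0.02 itself counts as "not high" and keeps
#' the potentiation protocol.
#'
#' @param p_constitutive constitutive open probability in \[0, 1\];
#'   vectorized.
#' @param threshold protocol switch point (default 0.02).
#' @return Character vector, `"direct_activation"` or `"potentiation"`.
#' @export
select_protocol <- function(p_constitutive, threshold = 0.02) {
  if (any(!is.finite(p_constitutive)) || any(p_constitutive < 0) ||
      any(p_constitutive > 1)) {
    stop("'p_constitutive' must lie in [0, 1]", call. = FALSE)
  }
  ifelse(p_constitutive > threshold, "direct_activation", "potentiation")
}

.PROFILE_COLUMNS <- c("cell_id", "receptor", "compound", "p_constitutive",
                      "p_background", "p_modulated", "protocol")

#' Assemble and validate a table of per-cell activation profiles
#'
#' One row per cell x compound: the constitutive, background (low-GABA) and
#' modulated open probabilities, with the protocol derived from the
#' constitutive activity. Cells in the ambiguous constitutive band
#' \[0.01, 0.02\] — too active for the "ignore it" rule, not active enough
#' for direct activation — are flagged for audit (`band_flag`); their
#' background is used uncorrected.
#'
#' @param cell_id,receptor,compound character vectors (recycled).
#' @param p_constitutive,p_background,p_modulated probabilities in \[0, 1\].
#' @param band numeric length-2: the constitutive band that triggers the
#'   audit flag (default `c(0.01, 0.02)`).
#' @return A data.frame of class `cell_profiles` with columns `cell_id`,
#'   `receptor`, `compound`, `p_constitutive`, `p_background`,
#'   `p_modulated`, `protocol`, `band_flag`.
#' @export
cell_profiles <- function(cell_id, receptor, compound,
                          p_constitutive, p_background, p_modulated,
                          band = c(0.01, 0.02)) {
  stopifnot(length(band) == 2L, band[1] <= band[2])
  for (p in list(p_constitutive, p_background, p_modulated)) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
      stop("profile probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  protocol <- select_protocol(p_constitutive, threshold = band[2])
  out <- data.frame(
    cell_id = as.character(cell_id),
    receptor = as.character(receptor),
    compound = as.character(compound),
    p_constitutive = p_constitutive,
    p_background = p_background,
    p_modulated = p_modulated,
    protocol = protocol,
    band_flag = protocol == "potentiation" &
      p_constitutive >= band[1] & p_constitutive <= band[2],
    stringsAsFactors = FALSE
  )
  class(out) <- c("cell_profiles", "data.frame")
  out
}

.check_profiles <- function(profiles) {
  missing <- setdiff(.PROFILE_COLUMNS, names(profiles))
  if (length(missing)) {
    stop("profile table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(profiles)
}

#' Background open probability for modulation arithmetic
#'
#' For the potentiation protocol this is the measured low-GABA response,
#' used as-is (no constitutive correction when the constitutive activity is
#' below 0.01, and — flagged — in the 0.01–0.02 band). For direct
#' activation it is the constitutive open probability itself.
#'
#' @param profiles a [cell_profiles()] table.
#' @return Numeric vector, one background probability per row.
#' @export
background_pa <- function(profiles) {
  .check_profiles(profiles)
  ifelse(profiles$protocol == "direct_activation",
         profiles$p_constitutive, profiles$p_background)
}

#' Modulation as percent of control
#'
#' `100 * p_modulated / background`, where the background is chosen per
#' protocol by [background_pa()]. 100 means no effect; values above 100 mean
#' potentiation, below 100 inhibition.
#'
#' @param profiles a [cell_profiles()] table.
#' @return Numeric vector of percentages.
#' @export
modulation_percent <- function(profiles) {
  bg <- background_pa(profiles)
  if (any(bg <= 0)) {
    stop("zero background activation: modulation percent undefined",
         call. = FALSE)
  }
  100 * profiles$p_modulated / bg
}

# ---- amplitude-table interface ---------------------------------------------

.ZERO_CONDITION <- "picrotoxin"
.FULL_CONDITION <- "GABA+propofol"
.AMPLITUDE_COLUMNS <- c("cell_id", "receptor", "compound", "condition",
                        "amplitude_nA")

#' Read a per-cell amplitude table
#'
#' Comma-separated, header row, UTF-8; columns `cell_id`, `receptor`,
#' `compound`, `condition`, `amplitude_nA`. The conditions `"picrotoxin"`
#' and `"GABA+propofol"` are the per-cell zero- and full-activation anchors;
#' `"constitutive"`, `"low_GABA"` and `"compound"` are the measurements.
#'
#' @param path file path.
#' @return A data.frame of amplitude records.
#' @export
read_amplitude_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  missing <- setdiff(.AMPLITUDE_COLUMNS, names(tab))
  if (length(missing)) {
    stop("amplitude table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Convert amplitude records to activation profiles
#'
#' Groups records per cell, requires exactly one zero- and one
#' full-activation anchor per cell, normalizes the `constitutive`,
#' `low_GABA` and `compound` amplitudes against the anchors, and assembles
#' [cell_profiles()].
#'
#' @param records amplitude table as from [read_amplitude_table()].
#' @param band audit band passed to [cell_profiles()].
#' @return A `cell_profiles` data.frame.
#' @export
profiles_from_amplitudes <- function(records, band = c(0.01, 0.02)) {
  missing <- setdiff(.AMPLITUDE_COLUMNS, names(records))
  if (length(missing)) {
    stop("amplitude table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  split_key <- interaction(records$cell_id, records$compound, drop = TRUE)
  rows <- lapply(split(records, split_key), function(cell) {
    get1 <- function(cond, required = TRUE) {
      amp <- cell$amplitude_nA[cell$condition == cond]
      if (length(amp) != 1L) {
        if (required || length(amp) > 1L) {
          stop(sprintf("cell '%s': expected exactly one '%s' record, found %d",
                       cell$cell_id[1], cond, length(amp)), call. = FALSE)
        }
        return(NA_real_)
      }
      amp
    }
    zero <- get1(.ZERO_CONDITION)
    full <- get1(.FULL_CONDITION)
    norm <- function(a) if (is.na(a)) NA_real_ else
      normalize_amplitude(a, zero, full)
    p_const <- norm(get1("constitutive", required = FALSE))
    p_bg <- norm(get1("low_GABA", required = FALSE))
    p_mod <- norm(get1("compound"))
    if (is.na(p_const)) p_const <- 0
    if (is.na(p_bg)) p_bg <- p_const
    data.frame(cell_id = cell$cell_id[1], receptor = cell$receptor[1],
               compound = cell$compound[1], p_constitutive = p_const,
               p_background = p_bg, p_modulated = p_mod,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  cell_profiles(tab$cell_id, tab$receptor, tab$compound,
                tab$p_constitutive, tab$p_background, tab$p_modulated,
                band = band)
}

#' Write an activation-profile table to CSV
#'
#' @param profiles a [cell_profiles()] table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  .check_profiles(profiles)
  utils::write.csv(as.data.frame(profiles), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an activation-profile table from CSV
#'
#' @param path file path, as written by [write_profile_table()].
#' @param band audit band passed to [cell_profiles()].
#' @return A `cell_profiles` data.frame.
#' @export
read_profile_table <- function(path, band = c(0.01, 0.02)) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  .check_profiles(tab)
  cell_profiles(tab$cell_id, tab$receptor, tab$compound,
                tab$p_constitutive, tab$p_background, tab$p_modulated,
                band = band)
}
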