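#' Day-1-referenced consistency check of rigid-registration transforms
#'
#' Daily scans are rigidly registered to the planning image; once the first
#' fraction's registration is verified manually, later fractions can be
#' audited automatically by comparing their six transform parameters
#' (translations tx, ty, tz in mm; rotations rx, ry, rz in degrees) with the
#' day-1 values. For each fraction j > 1 and each parameter p the relative
#' deviation is
#' `d = |p_j - p_1| / max(|p_1|, floor)`;
#' a fraction is flagged `warn` (manual re-check advised) when any parameter
#' deviates by more than `threshold`. The floors (1 mm / 1 degree by
#' default) keep near-zero day-1 parameters from triggering spurious
#' warnings. Registration itself is a pluggable external step; this module
#' only audits its output.
#'
#' @param transforms data.frame with columns
#'   `patient_id, fraction, tx, ty, tz, rx, ry, rz` for one patient, sorted
#'   or sortable by fraction; fraction 1 must be present.
#' @param threshold relative-deviation threshold (default 0.05, i.e. 5%).
#' @param floors named vector with elements `translation` (mm) and
#'   `rotation` (degrees) used inside the max() denominator.
#' @return A data.frame (class `lrt_qc_report`) with one row per fraction:
#'   the six per-parameter relative deviations (`d_tx` ... `d_rz`), the
#'   maximum deviation, and `status` (`"pass"`/`"warn"`). The threshold and
#'   floors are attached as attributes.
#' @examples
#' tr <- data.frame(patient_id = "P1", fraction = 1:3,
#'                  tx = c(10, 10.2, 12), ty = 0, tz = 0,
#'                  rx = 1, ry = 1, rz = 1)
#' checkRegistrationConsistency(tr)
#' @export
checkRegistrationConsistency <- function(transforms, threshold = 0.05,
                                         floors = c(translation = 1,
                                                    rotation = 1)) {
  pars <- c("tx", "ty", "tz", "rx", "ry", "rz")
  need <- c("patient_id", "fraction", pars)
  if (!all(need %in% names(transforms)))
    stop("transforms must have columns ", paste(need, collapse = ","))
  if (length(unique(transforms$patient_id)) > 1)
    stop("one patient at a time; split by patient_id first")
  m <- as.matrix(transforms[order(transforms$fraction), pars])
  frac <- sort(transforms$fraction)
  if (frac[1] != 1)
    stop("reference error: day-1 (fraction 1) transform is missing")
  if (!all(is.finite(m))) stop("non-finite transform parameters")
  ref <- m[1, ]
  den <- pmax(abs(ref), rep(floors[c("translation", "rotation")],
                            each = 3))
  dev <- sweep(abs(sweep(m, 2, ref, "-")), 2, den, "/")
  dev[1, ] <- 0  # day 1 is its own reference
  maxdev <- apply(dev, 1, max)
  rep_ <- data.frame(patient_id = transforms$patient_id[1], fraction = frac,
                     stats::setNames(as.data.frame(dev), paste0("d_", pars)),
                     max_deviation = maxdev,
                     status = ifelse(maxdev > threshold, "warn", "pass"),
                     row.names = NULL)
  attr(rep_, "threshold") <- threshold
  attr(rep_, "floors") <- floors
  class(rep_) <- c("lrt_qc_report", "data.frame")
  rep_
}

#' Read rigid-transform parameters from CSV
#'
#' @param path CSV with columns `patient_id,fraction,tx,ty,tz,rx,ry,rz`.
#' @return A data.frame.
#' @export
readTransforms <- function(path) {
  as.data.frame(data.table::fread(path, colClasses = list(
    character = "patient_id")))
}

#' Run the registration QC over a multi-patient transform table
#'
#' @param transforms data.frame as in [checkRegistrationConsistency()],
#'   possibly covering several patients.
#' @inheritParams checkRegistrationConsistency
#' @return A single data.frame of per-fraction QC rows for all patients.
#' @export
registrationQC <- function(transforms, threshold = 0.05,
                           floors = c(translation = 1, rotation = 1)) {
  parts <- lapply(split(transforms, transforms$patient_id),
                  checkRegistrationConsistency,
                  threshold = threshold, floors = floors)
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  attr(out, "threshold") <- threshold
  attr(out, "floors") <- floors
  out
}
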