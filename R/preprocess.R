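# ---------------------------------------------------------------------------
# Probe-level filtering and beta <-> M conversion, applied before calling.
# ---------------------------------------------------------------------------

new_filter_report <- function(n_input, n_detection = 0L, n_snp = 0L,
                              n_sex = 0L, n_control = 0L, n_missing = 0L) {
  n_retained <- n_input - n_detection - n_snp - n_sex - n_control - n_missing
  structure(list(n_input = as.integer(n_input),
                 n_removed_detection = as.integer(n_detection),
                 n_removed_snp = as.integer(n_snp),
                 n_removed_sex = as.integer(n_sex),
                 n_removed_control_inconsistent = as.integer(n_control),
                 n_removed_missing = as.integer(n_missing),
                 n_retained = as.integer(n_retained)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Probe filter report\n")
  cat(sprintf("  input:                %d\n", x$n_input))
  cat(sprintf("  removed detection:    %d\n", x$n_removed_detection))
  cat(sprintf("  removed SNP overlap:  %d\n", x$n_removed_snp))
  cat(sprintf("  removed sex chrom:    %d\n", x$n_removed_sex))
  cat(sprintf("  removed inconsistent: %d\n", x$n_removed_control_inconsistent))
  cat(sprintf("  removed missing:      %d\n", x$n_removed_missing))
  cat(sprintf("  retained:             %d\n", x$n_retained))
  invisible(x)
}

#' Filter probes on detection quality, SNP overlap and sex chromosomes
#'
#' A probe is removed if (in this order of attribution, each probe counted
#' once under the first matching reason):
#' 1. its detection p-value exceeds `p_threshold` in *any* sample,
#' 2. it overlaps a known SNP (`snp_overlap` in the manifest),
#' 3. it lies on a sex chromosome (`sex_chrom`),
#' 4. its beta value is missing in any sample.
#'
#' The per-sample "any" rule for detection is the strictest common default;
#' relax by pre-masking the detection matrix if a fraction-based rule is
#' preferred.
#'
#' @param beta a [beta_matrix()].
#' @param manifest a [probe_manifest()] covering every probe in `beta`.
#' @param detection_p optional numeric matrix of detection p-values with the
#'   same dimnames as `beta` (samples may be a superset).
#' @param p_threshold detection p-value cutoff (default 0.01).
#' @return list with elements `beta` (filtered matrix) and `report`
#'   (a `filter_report`).
#' @export
filter_probes <- function(beta, manifest, detection_p = NULL,
                          p_threshold = 0.01) {
  units <- rownames(beta)
  absent <- setdiff(units, manifest$probe_id)
  if (length(absent) > 0)
    stop("probes absent from manifest: ",
         paste(utils::head(absent, 10), collapse = ", "),
         if (length(absent) > 10) sprintf(" (and %d more)",
                                          length(absent) - 10) else "")
  man <- manifest[match(units, manifest$probe_id), ]

  fail_det <- rep(FALSE, length(units))
  if (!is.null(detection_p)) {
    dp <- as.matrix(detection_p)
    missing_units <- setdiff(units, rownames(dp))
    if (length(missing_units) > 0)
      stop("detection p matrix lacks probes: ",
           paste(utils::head(missing_units, 5), collapse = ", "))
    dp <- dp[units, intersect(colnames(dp), colnames(beta)), drop = FALSE]
    fail_det <- apply(dp, 1, function(p) any(!is.na(p) & p > p_threshold))
  }
  fail_snp <- man$snp_overlap
  fail_sex <- man$sex_chrom
  fail_missing <- apply(unclass(beta), 1, anyNA)

  # first-matching attribution: detection -> SNP -> sex -> missing
  reason <- rep("keep", length(units))
  reason[fail_missing] <- "missing"
  reason[fail_sex] <- "sex"
  reason[fail_snp] <- "snp"
  reason[fail_det] <- "detection"

  keep <- reason == "keep"
  report <- new_filter_report(length(units),
                              n_detection = sum(reason == "detection"),
                              n_snp = sum(reason == "snp"),
                              n_sex = sum(reason == "sex"),
                              n_missing = sum(reason == "missing"))
  list(beta = beta_matrix(unclass(beta)[keep, , drop = FALSE]),
       report = report)
}

#' Remove probes with inconsistent control-panel methylation
#'
#' A probe is removed when any single control's beta deviates from the
#' arithmetic mean of the control betas by more than `max_dev` at that
#' probe.  Note the asymmetry with calling, which uses the control *median*
#' for the delta-beta statistic: both conventions are kept deliberately.
#'
#' @param beta a [beta_matrix()].
#' @param sheet a [sample_sheet()] with at least two controls present in
#'   `beta`.
#' @param max_dev maximum tolerated absolute deviation on the beta scale
#'   (default 0.2).
#' @param cell_type control panel restriction passed to [control_ids()]
#'   (default `"iPSC"`); set `NULL` to use all controls.
#' @return list with `beta` (filtered) and `report` (a `filter_report` whose
#'   only non-zero removal bucket is `n_removed_control_inconsistent`).
#' @export
control_consistency_filter <- function(beta, sheet, max_dev = 0.2,
                                       cell_type = "iPSC") {
  ctrl <- intersect(control_ids(sheet, cell_type), colnames(beta))
  if (length(ctrl) < 2)
    stop("control consistency filter requires >= 2 control samples")
  cb <- unclass(beta)[, ctrl, drop = FALSE]
  mu <- rowMeans(cb, na.rm = TRUE)
  dev <- abs(cb - mu)
  bad <- apply(dev, 1, function(d) any(!is.na(d) & d > max_dev))
  report <- new_filter_report(nrow(beta), n_control = sum(bad))
  list(beta = beta_matrix(unclass(beta)[!bad, , drop = FALSE]),
       report = report)
}

#' Convert beta values to M-values
#'
#' `M = log2(beta / (1 - beta))` after clipping beta into
#' `[eps, 1 - eps]`.  Clipping keeps M finite at beta of exactly 0 or 1,
#' which do occur on arrays; eps = 0.001 caps |M| at about 9.96 with
#' negligible distortion elsewhere.  Missing values propagate.
#'
#' @param beta a [beta_matrix()] (or plain numeric vector/matrix).
#' @param eps clipping bound in (0, 0.5).
#' @return an [m_matrix()] (or numeric of the same shape as the input).
#' @export
beta_to_m <- function(beta, eps = 0.001) {
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0 || eps >= 0.5)
    stop("eps must be a single value in (0, 0.5)")
  x <- unclass(beta)
  x <- pmin(pmax(x, eps), 1 - eps)
  m <- log2(x / (1 - x))
  if (inherits(beta, "beta_matrix")) m_matrix(m) else m
}

#' Convert M-values back to beta values
#'
#' Inverse of [beta_to_m()] on the clipped range:
#' `beta = 2^M / (1 + 2^M)`.
#'
#' @param m an [m_matrix()] or numeric.
#' @return numeric beta values in (0, 1), a [beta_matrix()] if the input is
#'   an `m_matrix`.
#' @export
m_to_beta <- function(m) {
  x <- unclass(m)
  b <- 1 / (1 + 2^(-x))
  if (inherits(m, "m_matrix")) beta_matrix(b) else b
}
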