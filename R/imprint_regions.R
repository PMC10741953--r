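# ---------------------------------------------------------------------------
# Imprinted-DMR (iDMR) analysis: region filtering, region-level calling,
# control-level grouping, and recovery classification in corrected clones.
# ---------------------------------------------------------------------------

#' Filter iDMR regions on probe coverage and an exclusion list
#'
#' Regions covered by fewer than `min_probes` manifest probes are removed,
#' then any region named in `exclude` (e.g. a polymorphic locus) is
#' removed.  Order is preserved; the operation is idempotent.
#'
#' @param regions a [region_set()].
#' @param manifest a [probe_manifest()].
#' @param min_probes minimum probes per region (default 3).
#' @param exclude character vector of region names to drop; names absent
#'   from `regions` give a warning, not an error.
#' @return the filtered [region_set()], with a `n_probes` attribute holding
#'   the per-region probe counts of the input.
#' @export
filter_idmr_regions <- function(regions, manifest, min_probes = 3,
                                exclude = character(0)) {
  counts <- vapply(probes_in_regions(regions, manifest), length, integer(1))
  keep <- counts >= min_probes
  missing_excl <- setdiff(exclude, regions$name)
  if (length(missing_excl) > 0)
    warning("exclude name(s) not present: ",
            paste(missing_excl, collapse = ", "))
  keep <- keep & !(regions$name %in% exclude)
  out <- region_set(as.data.frame(regions)[keep, , drop = FALSE])
  attr(out, "n_probes") <- counts
  out
}

#' Region-level beta averages for a region set
#'
#' Averages probe betas over the probes contained in each region, keeping
#' regions with at least `min_probes` probes.
#'
#' @param beta probe-level [beta_matrix()].
#' @param regions a [region_set()].
#' @param manifest a [probe_manifest()].
#' @param min_probes minimum probes per region (default 3).
#' @return a [beta_matrix()] with one row per retained region.
#' @export
region_beta <- function(beta, regions, manifest, min_probes = 3) {
  pr <- probes_in_regions(regions, manifest)
  membership <- stats::setNames(
    rep(names(pr), lengths(pr)), unlist(pr, use.names = FALSE))
  membership <- membership[names(membership) %in% rownames(beta)]
  if (length(membership) == 0)
    stop("no region probe is present in the beta matrix")
  aggregate_units(beta, membership, min_cpgs = min_probes)
}

#' Group regions by their control-panel methylation level
#'
#' Regions are partitioned by the mean control beta:
#' `high` at >= 0.60, `intermediate` in \[0.40, 0.60), `low` below 0.40.
#' High regions are those hypermethylated in control iPSCs; intermediate
#' regions sit near the 50% level expected of imprinting control regions.
#'
#' @param region_beta region-level [beta_matrix()] containing the controls.
#' @param sheet a [sample_sheet()].
#' @param cell_type control panel restriction (default `"iPSC"`).
#' @param high,low group boundaries on the beta scale (defaults 0.60 and
#'   0.40).
#' @return data.frame of class `region_groups` with columns `name`,
#'   `group`, `control_mean_beta`.
#' @export
classify_region_groups <- function(region_beta, sheet, cell_type = "iPSC",
                                   high = 0.60, low = 0.40) {
  ctrl <- intersect(control_ids(sheet, cell_type), colnames(region_beta))
  if (length(ctrl) < 1) stop("no control samples in region matrix")
  mu <- rowMeans(unclass(region_beta)[, ctrl, drop = FALSE], na.rm = TRUE)
  group <- ifelse(mu >= high, "high",
                  ifelse(mu >= low, "intermediate", "low"))
  out <- data.frame(name = rownames(region_beta), group = group,
                    control_mean_beta = mu, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("region_groups", "data.frame"))
}

#' Region-level differential methylation calling
#'
#' The probe-level statistic applied to region beta averages: the region
#' averages are converted to M-values, a region-level control reference is
#' built, and each requested sample is called with the same
#' `|dM| > k * SD` and `|dbeta| > delta` rule.
#'
#' @param region_beta region-level [beta_matrix()] (e.g. from
#'   [region_beta()]).
#' @param sheet a [sample_sheet()].
#' @param sample_ids samples to call (default: patients and corrected
#'   clones present in the matrix).
#' @param k,delta calling thresholds.
#' @param cell_type control panel restriction (default `"iPSC"`).
#' @return list with `ref` (region-level `control_reference`) and `calls`
#'   (a `dm_calls` data.frame).
#' @export
call_region_dm <- function(region_beta, sheet, sample_ids = NULL,
                           k = 3, delta = 0.2, cell_type = "iPSC") {
  if (is.null(sample_ids))
    sample_ids <- intersect(
      sheet$sample_id[sheet$role %in% c("patient", "corrected")],
      colnames(region_beta))
  m <- beta_to_m(region_beta)
  ref <- build_reference(region_beta, m, sheet, cell_type = cell_type)
  calls <- call_dm_samples(region_beta, m, ref, sample_ids,
                           k = k, delta = delta)
  list(ref = ref, calls = calls)
}

#' Classify methylation recovery in corrected clones
#'
#' For every unit differentially methylated in a patient and every
#' corrected clone of that patient, the unit is "recovered" in the clone
#' when the clone's beta lies within `delta` of the control median:
#' `|beta_corrected - median_beta_control| < delta` (strict).
#'
#' @param patient_calls a `dm_calls` data.frame covering the patients.
#' @param corrected_beta [beta_matrix()] (probe, bin or region level —
#'   whatever level `patient_calls` was made at) containing the corrected
#'   clones.
#' @param ref the `control_reference` used for the patient calls.
#' @param sheet a [sample_sheet()].
#' @param delta recovery threshold on the beta scale (default 0.2).
#' @return data.frame of class `recovery_calls` with columns `unit_id`,
#'   `patient_id`, `corrected_id`, `patient_status`,
#'   `corrected_delta_beta`, `recovered`.
#' @export
classify_recovery <- function(patient_calls, corrected_beta, ref, sheet,
                              delta = 0.2) {
  pats <- intersect(unique(patient_calls$sample_id), patient_ids(sheet))
  rows <- list()
  for (p in pats) {
    clones <- intersect(clones_of(sheet, p), colnames(corrected_beta))
    dm <- patient_calls[patient_calls$sample_id == p &
                          patient_calls$status != "unchanged", ,
                        drop = FALSE]
    if (nrow(dm) == 0 || length(clones) == 0) next
    ridx <- match(dm$unit_id, ref$unit_id)
    if (anyNA(ridx))
      stop("patient dm unit(s) missing from the reference")
    for (cl in clones) {
      cb <- unclass(corrected_beta)[dm$unit_id, cl]
      d <- cb - ref$median_beta[ridx]
      rows[[length(rows) + 1]] <- data.frame(
        unit_id = dm$unit_id, patient_id = p, corrected_id = cl,
        patient_status = dm$status, corrected_delta_beta = d,
        recovered = !is.na(d) & abs(d) < delta,
        stringsAsFactors = FALSE)
    }
  }
  clones_without_calls <- sheet$sample_id[
    sheet$role == "corrected" & !(sheet$parent_patient %in% pats)]
  if (length(clones_without_calls) > 0 &&
      any(clones_without_calls %in% colnames(corrected_beta)))
    stop("corrected clone(s) whose parent patient has no calls: ",
         paste(intersect(clones_without_calls, colnames(corrected_beta)),
               collapse = ", "))
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(unit_id = character(0), patient_id = character(0),
               corrected_id = character(0), patient_status = character(0),
               corrected_delta_beta = numeric(0), recovered = logical(0))
  rownames(out) <- NULL
  structure(out, class = c("recovery_calls", "data.frame"))
}

#' Summarise recovery percentages
#'
#' Percent of differentially methylated units recovered per corrected
#' clone, optionally broken down by a unit classification (e.g. genomic
#' element or iDMR group), plus the count of units shared by all patients
#' that recovered in every corrected clone.
#'
#' @param recovery a `recovery_calls` data.frame.
#' @param grouping optional named character vector mapping unit id ->
#'   class; units without a class are summarised under `"(unclassified)"`.
#' @return list of class `recovery_summary` with:
#'   `per_clone` — data.frame (corrected_id, n, n_recovered, pct_recovered);
#'   `per_class` — same plus `class`, `NULL` when no grouping is given
#'   (classes with zero calls are omitted);
#'   `shared` — list with `n_shared` (units dm in every patient),
#'   `n_recovered_all` (those recovered in every clone of every patient)
#'   and `pct`.
#' @export
recovery_summary <- function(recovery, grouping = NULL) {
  if (nrow(recovery) == 0) stop("no recovery calls to summarise")
  agg <- function(df, by) {
    sp <- split(df, df[by], drop = TRUE)
    out <- do.call(rbind, lapply(sp, function(s) {
      cbind(unique(s[, by, drop = FALSE]),
            data.frame(n = nrow(s), n_recovered = sum(s$recovered),
                       pct_recovered = 100 * mean(s$recovered)))
    }))
    rownames(out) <- NULL
    out
  }
  per_clone <- agg(recovery, "corrected_id")

  per_class <- NULL
  if (!is.null(grouping)) {
    cls <- unname(grouping[recovery$unit_id])
    cls[is.na(cls)] <- "(unclassified)"
    rec2 <- recovery
    rec2$class <- cls
    per_class <- agg(rec2, c("corrected_id", "class"))
  }

  patients <- unique(recovery$patient_id)
  by_unit <- split(recovery, recovery$unit_id)
  shared_units <- names(by_unit)[vapply(by_unit, function(u)
    length(unique(u$patient_id)) == length(patients), logical(1))]
  n_rec_all <- sum(vapply(by_unit[shared_units],
                          function(u) all(u$recovered), logical(1)))
  shared <- list(n_shared = length(shared_units),
                 n_recovered_all = n_rec_all,
                 pct = if (length(shared_units) > 0)
                   100 * n_rec_all / length(shared_units) else NA_real_)
  structure(list(per_clone = per_clone, per_class = per_class,
                 shared = shared),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat("Recovery per corrected clone:\n")
  print(x$per_clone, row.names = FALSE)
  if (!is.null(x$per_class)) {
    cat("Recovery per class:\n")
    print(x$per_class, row.names = FALSE)
  }
  cat(sprintf("Shared dm units: %d; recovered in all clones: %d (%.1f%%)\n",
              x$shared$n_shared, x$shared$n_recovered_all, x$shared$pct))
  invisible(x)
}
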