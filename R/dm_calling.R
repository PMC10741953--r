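# ---------------------------------------------------------------------------
# Control-panel reference construction, differential methylation calling,
# 500 bp genome binning, and cluster detection.
#
# The statistic: a unit (CpG, bin or region) in a test sample is called
# differentially methylated when BOTH
#   |dM|    = |M_sample - mean(M_controls)|   >  k * SD(M_controls)   and
#   |dbeta| = |beta_sample - median(beta_controls)| > delta
# hold (strict inequalities).  Hyper if dbeta > delta, hypo if
# dbeta < -delta.  dM is taken against the control MEAN on the M scale and
# dbeta against the control MEDIAN on the beta scale; the asymmetry is
# intentional and matches the reference procedure.
# ---------------------------------------------------------------------------

#' Build the control-panel reference
#'
#' Per unit: mean and sample standard deviation (n - 1 denominator) of the
#' control M-values, plus the median control beta.  Units missing in any
#' control are dropped with a warning.
#'
#' @param beta a [beta_matrix()].
#' @param m the matching [m_matrix()] (same dimnames).
#' @param sheet a [sample_sheet()] with >= 2 controls present in `beta`.
#' @param cell_type control panel restriction (default `"iPSC"`); `NULL`
#'   uses all control-role samples.
#' @return data.frame of class `control_reference` with columns `unit_id`,
#'   `mean_m`, `sd_m`, `median_beta`, `n_controls`.
#' @export
build_reference <- function(beta, m, sheet, cell_type = "iPSC") {
  ctrl <- intersect(control_ids(sheet, cell_type), colnames(beta))
  if (length(ctrl) < 2)
    stop("reference construction requires >= 2 control samples")
  cb <- unclass(beta)[, ctrl, drop = FALSE]
  cm <- unclass(m)[, ctrl, drop = FALSE]
  complete <- !apply(cb, 1, anyNA) & !apply(cm, 1, anyNA)
  if (any(!complete))
    warning(sum(!complete), " unit(s) missing in a control sample dropped",
            " from the reference")
  cb <- cb[complete, , drop = FALSE]
  cm <- cm[complete, , drop = FALSE]
  ref <- data.frame(
    unit_id = rownames(cb),
    mean_m = rowMeans(cm),
    sd_m = apply(cm, 1, stats::sd),
    median_beta = apply(cb, 1, stats::median),
    n_controls = length(ctrl),
    stringsAsFactors = FALSE)
  rownames(ref) <- NULL
  structure(ref, class = c("control_reference", "data.frame"))
}

#' Call differential methylation for one sample against the reference
#'
#' @param beta a [beta_matrix()] containing `sample_id`.
#' @param m the matching [m_matrix()].
#' @param ref a `control_reference` from [build_reference()].
#' @param sample_id sample to call.
#' @param k SD multiplier on the M scale (default 3).
#' @param delta beta-scale effect threshold (default 0.2).
#' @return data.frame of class `dm_calls` with columns `unit_id`,
#'   `sample_id`, `delta_m`, `delta_beta`, `sd_m`, `status`
#'   (hyper/hypo/unchanged).  Units with `sd_m == 0` (identical controls)
#'   make the SD criterion vacuous; they are called on the beta criterion
#'   alone and their count is attached as `attr(, "n_sd_zero")` with a
#'   warning.  Units missing in the sample are `unchanged` with `NA` deltas.
#' @export
call_dm <- function(beta, m, ref, sample_id, k = 3, delta = 0.2) {
  if (!(sample_id %in% colnames(beta)))
    stop("unknown sample: ", sample_id)
  units <- intersect(ref$unit_id, rownames(beta))
  r <- ref[match(units, ref$unit_id), ]
  b <- unclass(beta)[units, sample_id]
  mm <- unclass(m)[units, sample_id]

  delta_m <- mm - r$mean_m
  delta_beta <- b - r$median_beta
  sd_zero <- r$sd_m == 0
  n_sd_zero <- sum(sd_zero, na.rm = TRUE)
  if (n_sd_zero > 0)
    warning(n_sd_zero, " unit(s) with sd_m = 0: SD criterion vacuous,",
            " called on |delta beta| alone")
  pass_m <- ifelse(sd_zero, abs(delta_m) > 0, abs(delta_m) > k * r$sd_m)
  status <- rep("unchanged", length(units))
  status[!is.na(delta_beta) & !is.na(pass_m) & pass_m &
           delta_beta > delta] <- "hyper"
  status[!is.na(delta_beta) & !is.na(pass_m) & pass_m &
           delta_beta < -delta] <- "hypo"
  out <- data.frame(unit_id = units, sample_id = sample_id,
                    delta_m = delta_m, delta_beta = delta_beta,
                    sd_m = r$sd_m, status = status,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- structure(out, class = c("dm_calls", "data.frame"))
  attr(out, "n_sd_zero") <- n_sd_zero
  out
}

#' Call differential methylation for several samples
#'
#' Convenience wrapper around [call_dm()]; rows are stacked per sample.
#'
#' @inheritParams call_dm
#' @param sample_ids samples to call (default: all non-control samples in
#'   `beta` that appear in `ref`-compatible matrices).
#' @return a `dm_calls` data.frame.
#' @export
call_dm_samples <- function(beta, m, ref, sample_ids, k = 3, delta = 0.2) {
  out <- do.call(rbind, lapply(sample_ids, function(s)
    call_dm(beta, m, ref, s, k = k, delta = delta)))
  structure(out, class = c("dm_calls", "data.frame"))
}

#' Assign probes to fixed-width genome bins
#'
#' Bins tile each chromosome from coordinate 0 in `bin_size` steps; the
#' probe at position p falls in bin `[floor(p / bin_size) * bin_size,
#' + bin_size)` (half-open).
#'
#' @param manifest a [probe_manifest()].
#' @param bin_size bin width in bp (default 500).
#' @return data.frame with columns `probe_id`, `chrom`, `pos`, `bin_id`
#'   (`"chrom:start-end"`), `bin_start`.
#' @export
assign_bins <- function(manifest, bin_size = 500) {
  start <- (manifest$pos %/% bin_size) * bin_size
  data.frame(probe_id = manifest$probe_id,
             chrom = manifest$chrom,
             pos = manifest$pos,
             bin_id = sprintf("%s:%d-%d", manifest$chrom, start,
                              start + bin_size),
             bin_start = start,
             stringsAsFactors = FALSE)
}

#' Average unit values within groups (bins or regions)
#'
#' The group value for a sample is the unweighted mean of the member
#' probes' betas.  A group enters the output only if it has at least
#' `min_cpgs` members; within a retained group, a sample's value is `NA`
#' whenever any member is missing in that sample (per-sample completeness).
#'
#' @param beta a [beta_matrix()] at probe level.
#' @param membership named character vector or list mapping probe id ->
#'   group id (probes not mapped are ignored).
#' @param min_cpgs minimum members per group (2 for 500 bp bins, 3 for
#'   regions).
#' @return a [beta_matrix()] over groups (rows ordered by first appearance
#'   of each group among `beta`'s units).
#' @export
aggregate_units <- function(beta, membership, min_cpgs = 2) {
  membership <- unlist(membership)
  if (length(membership) == 0) stop("empty membership")
  probes <- intersect(rownames(beta), names(membership))
  if (length(probes) == 0) stop("membership covers no unit of the matrix")
  grp <- membership[probes]
  counts <- table(grp)
  keep_groups <- names(counts)[counts >= min_cpgs]
  # preserve order of first appearance along the probe axis
  keep_groups <- unique(grp)[unique(grp) %in% keep_groups]
  if (length(keep_groups) == 0)
    return(beta_matrix(matrix(numeric(0), nrow = 0, ncol = ncol(beta),
                              dimnames = list(NULL, colnames(beta)))))
  vals <- unclass(beta)[probes, , drop = FALSE]
  out <- matrix(NA_real_, nrow = length(keep_groups), ncol = ncol(beta),
                dimnames = list(keep_groups, colnames(beta)))
  for (g in keep_groups) {
    sub <- vals[grp == g, , drop = FALSE]
    mns <- colMeans(sub)            # NA if any member missing in a sample
    out[g, ] <- mns
  }
  beta_matrix(out)
}

#' Detect clusters of contiguous differentially methylated bins
#'
#' Bins are contiguous when they share a chromosome and their starts differ
#' by exactly `bin_size` (bins separated by an excluded low-coverage bin are
#' NOT contiguous).  Maximal runs of at least `min_bins` contiguous dm bins
#' form clusters; remaining dm bins are isolated.
#'
#' @param dm_bins data.frame with columns `chrom`, `start` (and optionally
#'   `bin_id`), one row per differentially methylated bin; duplicates are
#'   collapsed.
#' @param min_bins minimum bins per cluster (default 2).
#' @param bin_size bin width (default 500).
#' @return list of class `cluster_set` with `clusters` (list of data.frames,
#'   each a run of bins) and `isolated` (data.frame of bins in no cluster).
#' @export
find_clusters <- function(dm_bins, min_bins = 2, bin_size = 500) {
  dm_bins <- unique(dm_bins[, intersect(c("chrom", "start", "bin_id"),
                                        names(dm_bins)), drop = FALSE])
  dm_bins <- dm_bins[order(dm_bins$chrom, dm_bins$start), , drop = FALSE]
  rownames(dm_bins) <- NULL
  n <- nrow(dm_bins)
  clusters <- list()
  isolated <- dm_bins[0, , drop = FALSE]
  if (n > 0) {
    new_run <- c(TRUE, dm_bins$chrom[-1] != dm_bins$chrom[-n] |
                   dm_bins$start[-1] != dm_bins$start[-n] + bin_size)
    run_id <- cumsum(new_run)
    for (r in split(seq_len(n), run_id)) {
      if (length(r) >= min_bins) {
        clusters[[length(clusters) + 1]] <- dm_bins[r, , drop = FALSE]
      } else {
        isolated <- rbind(isolated, dm_bins[r, , drop = FALSE])
      }
    }
  }
  rownames(isolated) <- NULL
  structure(list(clusters = clusters, isolated = isolated),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d cluster(s) containing %d bin(s); %d isolated\n",
              length(x$clusters),
              sum(vapply(x$clusters, nrow, integer(1))),
              nrow(x$isolated)))
  invisible(x)
}

#' Bin-level differential methylation calling
#'
#' Aggregates probe betas into bins (>= `min_cpgs` CpGs), converts the bin
#' averages to M-values, rebuilds a bin-level control reference and applies
#' the same |dM| / |dbeta| statistic as at probe level.
#'
#' @param beta probe-level [beta_matrix()].
#' @param manifest a [probe_manifest()].
#' @param sheet a [sample_sheet()].
#' @param sample_ids samples to call (default: patients and corrected).
#' @param bin_size bin width (default 500).
#' @param min_cpgs minimum CpGs per bin (default 2).
#' @param k,delta calling thresholds.
#' @param cell_type control panel restriction (default `"iPSC"`).
#' @return list with `bin_beta` (bin-level beta matrix), `ref` (bin-level
#'   reference), `calls` (a `dm_calls` data.frame), `bin_map` (output of
#'   [assign_bins()] restricted to the matrix probes).
#' @export
call_bins <- function(beta, manifest, sheet, sample_ids = NULL,
                      bin_size = 500, min_cpgs = 2, k = 3, delta = 0.2,
                      cell_type = "iPSC") {
  if (is.null(sample_ids))
    sample_ids <- intersect(
      sheet$sample_id[sheet$role %in% c("patient", "corrected")],
      colnames(beta))
  bins <- assign_bins(manifest, bin_size)
  bins <- bins[bins$probe_id %in% rownames(beta), , drop = FALSE]
  membership <- stats::setNames(bins$bin_id, bins$probe_id)
  bin_beta <- aggregate_units(beta, membership, min_cpgs = min_cpgs)
  bin_m <- beta_to_m(bin_beta)
  ref <- build_reference(bin_beta, bin_m, sheet, cell_type = cell_type)
  calls <- call_dm_samples(bin_beta, bin_m, ref, sample_ids,
                           k = k, delta = delta)
  list(bin_beta = bin_beta, ref = ref, calls = calls, bin_map = bins)
}

#' Parse "chrom:start-end" bin ids back into coordinates
#'
#' @param bin_id character vector of bin identifiers.
#' @return data.frame with `bin_id`, `chrom`, `start`, `end`.
#' @export
parse_bin_ids <- function(bin_id) {
  m <- regmatches(bin_id, regexec("^(.*):([0-9]+)-([0-9]+)$", bin_id))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) stop("malformed bin id: ", bin_id[bad][1])
  data.frame(bin_id = bin_id,
             chrom = vapply(m, `[`, character(1), 2),
             start = as.integer(vapply(m, `[`, character(1), 3)),
             end = as.integer(vapply(m, `[`, character(1), 4)),
             stringsAsFactors = FALSE)
}
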