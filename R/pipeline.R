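# ---------------------------------------------------------------------------
# End-to-end orchestration: preprocess -> reference -> CpG calls -> bin
# calls -> clusters -> iDMR analysis -> recovery -> annotation ->
# enrichment, with a JSON run manifest.
# ---------------------------------------------------------------------------

#' Run configuration for the full pipeline
#'
#' Collects input paths and every fixed threshold in one declarative
#' object.  Defaults are the reference procedure's printed constants.
#'
#' @param beta,manifest,regions,samples file paths (TSV / BED-like TSV).
#' @param detection optional detection p-value TSV path.
#' @param chip_counts optional ChIP count TSV path.
#' @param out_dir output directory.
#' @param k SD multiplier (default 3).
#' @param delta beta effect threshold (default 0.2).
#' @param p_detect detection p-value cutoff (default 0.01).
#' @param max_control_dev control-consistency cutoff (default 0.2).
#' @param min_cpgs_bin minimum CpGs per 500 bp bin (default 2).
#' @param min_probes_region minimum probes per region (default 3).
#' @param min_cluster_bins minimum bins per cluster (default 2).
#' @param recovery_delta recovery threshold (default 0.2).
#' @param bin_size bin width (default 500).
#' @param exclude_regions region names excluded by fiat (e.g. polymorphic
#'   loci).
#' @param control_cell_type cell type of the control panel (default iPSC).
#' @param chip_alternative one-sided direction for enrichment comparisons.
#' @param seed seed for any randomized step.
#' @return list of class `run_config`.
#' @export
run_config <- function(beta, manifest, regions, samples,
                       detection = NULL, chip_counts = NULL,
                       out_dir = "imprintscan_out",
                       k = 3, delta = 0.2, p_detect = 0.01,
                       max_control_dev = 0.2, min_cpgs_bin = 2,
                       min_probes_region = 3, min_cluster_bins = 2,
                       recovery_delta = 0.2, bin_size = 500,
                       exclude_regions = character(0),
                       control_cell_type = "iPSC",
                       chip_alternative = "greater",
                       seed = 1) {
  cfg <- as.list(environment())
  for (f in c("k", "delta", "p_detect", "max_control_dev", "min_cpgs_bin",
              "min_probes_region", "min_cluster_bins", "recovery_delta",
              "bin_size"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop(f, " must be positive")
  structure(cfg, class = "run_config")
}

write_stage_tsv <- function(x, dir, name) {
  utils::write.table(as.data.frame(x), file.path(dir, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Run the full pipeline
#'
#' Stages, in order: (1) probe filters, (2) control-consistency filter,
#' (3) control reference + per-CpG calls, (4) bin aggregation + bin calls,
#' (5) cluster detection, (6) iDMR region analysis (filter, groups, calls),
#' (7) recovery classification, (8) patient-overlap shuffle test,
#' (9) ChIP fold change + enrichment comparison (when counts are given).
#' All stage tables are written to `config$out_dir` together with a JSON
#' run manifest recording per-stage counts and timings.
#'
#' @param config a [run_config()].
#' @return list of class `run_result` with the stage outputs and `manifest`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  required <- c(config$beta, config$manifest, config$regions, config$samples,
                config$detection, config$chip_counts)
  missing_files <- required[!file.exists(required)]
  if (length(missing_files) > 0)
    stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest_log <- list(config = unclass(config),
                       package_version = as.character(
                         utils::packageVersion("imprintscan")),
                       stages = list())
  fail_point <- NULL
  result <- tryCatch({
    beta <- read_beta_matrix(config$beta)
    man <- read_manifest(config$manifest)
    regions <- read_regions(config$regions)
    sheet <- read_sample_sheet(config$samples)
    detection <- if (!is.null(config$detection)) {
      d <- utils::read.delim(config$detection, check.names = FALSE)
      dm <- as.matrix(d[, -1, drop = FALSE]); rownames(dm) <- d[[1]]; dm
    } else NULL

    # 1-2: filters ----------------------------------------------------------
    fail_point <- "preprocess"
    f1 <- filter_probes(beta, man, detection, config$p_detect)
    f2 <- control_consistency_filter(f1$beta, sheet,
                                     max_dev = config$max_control_dev,
                                     cell_type = config$control_cell_type)
    beta_f <- f2$beta
    m_f <- beta_to_m(beta_f)
    write_beta_matrix(beta_f, file.path(config$out_dir, "beta_filtered.tsv"),
                      id_col = "probe_id")
    manifest_log$stages$filter_probes <- unclass(f1$report)
    manifest_log$stages$control_consistency <- unclass(f2$report)

    # 3: reference + CpG calls ----------------------------------------------
    fail_point <- "cpg_calls"
    test_ids <- intersect(
      sheet$sample_id[sheet$role %in% c("patient", "corrected")],
      colnames(beta_f))
    ref <- build_reference(beta_f, m_f, sheet,
                           cell_type = config$control_cell_type)
    cpg_calls <- call_dm_samples(beta_f, m_f, ref, test_ids,
                                 k = config$k, delta = config$delta)
    write_stage_tsv(cpg_calls, config$out_dir, "cpg_calls.tsv")
    manifest_log$stages$cpg_calls <- list(
      n_units = nrow(ref),
      n_hypo = sum(cpg_calls$status == "hypo"),
      n_hyper = sum(cpg_calls$status == "hyper"))

    # 4: bins ----------------------------------------------------------------
    fail_point <- "bin_calls"
    binres <- call_bins(beta_f, man, sheet, sample_ids = test_ids,
                        bin_size = config$bin_size,
                        min_cpgs = config$min_cpgs_bin,
                        k = config$k, delta = config$delta,
                        cell_type = config$control_cell_type)
    write_stage_tsv(binres$calls, config$out_dir, "bin_calls.tsv")
    manifest_log$stages$bin_calls <- list(
      n_bins = nrow(binres$bin_beta),
      n_hypo = sum(binres$calls$status == "hypo"),
      n_hyper = sum(binres$calls$status == "hyper"))

    # 5: clusters, per patient ------------------------------------------------
    fail_point <- "clusters"
    patients <- intersect(patient_ids(sheet), test_ids)
    clusters <- lapply(stats::setNames(patients, patients), function(p) {
      dmb <- binres$calls[binres$calls$sample_id == p &
                            binres$calls$status != "unchanged", ]
      coords <- parse_bin_ids(dmb$unit_id)
      find_clusters(coords, min_bins = config$min_cluster_bins,
                    bin_size = config$bin_size)
    })
    manifest_log$stages$clusters <- lapply(clusters, function(cs)
      list(n_clusters = length(cs$clusters), n_isolated = nrow(cs$isolated)))

    # 6: iDMR analysis --------------------------------------------------------
    fail_point <- "idmr"
    regions_f <- filter_idmr_regions(regions, man,
                                     min_probes = config$min_probes_region,
                                     exclude = config$exclude_regions)
    rbeta <- region_beta(beta_f, regions_f, man,
                         min_probes = config$min_probes_region)
    groups <- classify_region_groups(rbeta, sheet,
                                     cell_type = config$control_cell_type)
    regcall <- call_region_dm(rbeta, sheet, sample_ids = test_ids,
                              k = config$k, delta = config$delta,
                              cell_type = config$control_cell_type)
    write_beta_matrix(rbeta, file.path(config$out_dir, "region_beta.tsv"),
                      id_col = "region")
    write_stage_tsv(groups, config$out_dir, "region_groups.tsv")
    write_stage_tsv(regcall$calls, config$out_dir, "region_calls.tsv")
    manifest_log$stages$idmr <- list(
      n_regions_input = nrow(regions), n_regions_retained = nrow(regions_f),
      n_hypo = sum(regcall$calls$status == "hypo" &
                     regcall$calls$sample_id %in% patients))

    # 7: recovery -------------------------------------------------------------
    fail_point <- "recovery"
    pat_region_calls <- regcall$calls[regcall$calls$sample_id %in% patients, ]
    recovery <- classify_recovery(pat_region_calls, rbeta, regcall$ref,
                                  sheet, delta = config$recovery_delta)
    rec_sum <- if (nrow(recovery) > 0)
      recovery_summary(recovery,
                       grouping = stats::setNames(groups$group, groups$name))
    else NULL
    write_stage_tsv(recovery, config$out_dir, "recovery_calls.tsv")
    if (!is.null(rec_sum))
      write_stage_tsv(rec_sum$per_clone, config$out_dir,
                      "recovery_summary.tsv")
    manifest_log$stages$recovery <- if (is.null(rec_sum))
      list(n_calls = 0) else list(
        n_calls = nrow(recovery),
        pct_recovered = rec_sum$per_clone$pct_recovered,
        shared_pct = rec_sum$shared$pct)

    # 8: patient overlap shuffle test -----------------------------------------
    fail_point <- "overlap"
    overlap <- NULL
    if (length(patients) >= 2) {
      dm_sets <- lapply(patients, function(p)
        cpg_calls$unit_id[cpg_calls$sample_id == p &
                            cpg_calls$status != "unchanged"])
      overlap <- shuffle_overlap_test(dm_sets[[1]], dm_sets[[2]],
                                      universe = ref$unit_id,
                                      n_perm = 999, seed = config$seed)
      manifest_log$stages$overlap <- unclass(overlap)
    }

    # 9: ChIP enrichment ------------------------------------------------------
    fail_point <- "enrichment"
    enrichment <- NULL
    if (!is.null(config$chip_counts)) {
      chip <- read_chip_counts(config$chip_counts)
      fc <- chip_fold_change(chip)
      conds <- unique(fc$condition)
      ref_cond <- if ("WT" %in% conds) "WT" else conds[1]
      comparisons <- lapply(setdiff(conds, ref_cond),
                            function(cc) c(cc, ref_cond))
      enrichment <- enrichment_compare(fc, comparisons,
                                       alternative = config$chip_alternative)
      write_stage_tsv(fc, config$out_dir, "chip_fc.tsv")
      write_stage_tsv(enrichment, config$out_dir, "enrichment_stats.tsv")
      manifest_log$stages$enrichment <- list(n_comparisons = nrow(enrichment))
    }

    fail_point <- NULL
    list(beta_filtered = beta_f, filter_reports = list(f1$report, f2$report),
         ref = ref, cpg_calls = cpg_calls, bins = binres,
         clusters = clusters, regions_filtered = regions_f,
         region_beta = rbeta, region_groups = groups,
         region_calls = regcall$calls, region_ref = regcall$ref,
         recovery = recovery, recovery_summary = rec_sum,
         overlap = overlap, enrichment = enrichment)
  }, error = function(e) {
    manifest_log$failed_at <<- fail_point
    manifest_log$error <<- conditionMessage(e)
    jsonlite::write_json(manifest_log,
                         file.path(config$out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    stop(e)
  })
  manifest_log$n_stages <- length(manifest_log$stages)
  jsonlite::write_json(manifest_log,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  result$manifest <- manifest_log
  class(result) <- "run_result"
  result
}
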