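# ---------------------------------------------------------------------------
# Truth-annotated synthetic data emulating a control/patient/corrected iPSC
# methylation-array study: a control panel with small inter-control
# variability, two patients sharing a subset of planted hypomethylated loci
# (contiguous bin runs, isolated bins, and imprinted regions), corrected
# clones in which a configurable fraction of planted loci regains control
# methylation, fibroblast-like samples with ~50% iDMR methylation, and ChIP
# IP/input counts elevated at hypomethylated iDMRs.
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Defaults encode the emulated study design: an 11-line control iPSC
#' panel, two patients with two corrected clones each, planted
#' hypomethylation of magnitude 0.4 on the beta scale, control noise SD
#' 0.02, fibroblast iDMR methylation near 50%, and 3x ChIP enrichment at
#' hypomethylated iDMRs.
#'
#' @param n_controls number of control iPSC lines (default 11).
#' @param n_patients number of patient iPSC lines (default 2).
#' @param clones_per_patient corrected clones per patient (default 2).
#' @param n_fibroblast_controls fibroblast control samples (default 3).
#' @param n_cpgs background CpGs outside iDMRs (default 4000; rounded down
#'   to an even count, two probes per 500 bp bin).
#' @param n_idmrs number of iDMR regions drawn from the bundled fixture
#'   (default 50, the fixture's full size).
#' @param idmr_group_fractions named fractions over `high`, `intermediate`,
#'   `low` control methylation groups; must sum to 1.
#' @param planted_hypo_fraction fraction of eligible (high-methylation)
#'   iDMRs and bins planted hypomethylated in the patients (default 0.2).
#' @param shared_fraction fraction of planted loci planted in *both*
#'   patients (default 0.7); the rest alternate between patients.
#' @param planted_effect beta-scale hypomethylation magnitude (default 0.4).
#' @param resistant_fraction fraction of planted loci that do NOT recover
#'   in corrected clones (default 0.25).
#' @param control_noise_sd beta-scale SD of the truncated Gaussian noise
#'   (default 0.02).
#' @param unstable_control_fraction fraction of iDMRs given one outlier
#'   control (-0.3 beta) to exercise the control-consistency filter
#'   (default 0.05).
#' @param fibroblast_idmr_level iDMR methylation in fibroblast samples
#'   (default 0.5).
#' @param chip_fc_at_hypo IP/input fold change at planted-hypo iDMRs
#'   (default 3.0; 1 elsewhere).
#' @param chip_base_count expected input read count per region (default
#'   200).
#' @param chip_depth library depth for IP and input (default 1e6).
#' @param chip_replicates replicates per condition (default 2).
#' @param n_snp_probes,n_sex_probes flagged probes added to exercise the
#'   probe filters (default 10 each).
#' @param bin_size genome bin width (default 500).
#' @param seed integer seed; every random draw derives from it.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_controls = 11,
                              n_patients = 2,
                              clones_per_patient = 2,
                              n_fibroblast_controls = 3,
                              n_cpgs = 4000,
                              n_idmrs = 50,
                              idmr_group_fractions = c(high = 0.5,
                                                       intermediate = 0.3,
                                                       low = 0.2),
                              planted_hypo_fraction = 0.2,
                              shared_fraction = 0.7,
                              planted_effect = 0.4,
                              resistant_fraction = 0.25,
                              control_noise_sd = 0.02,
                              unstable_control_fraction = 0.05,
                              fibroblast_idmr_level = 0.5,
                              chip_fc_at_hypo = 3.0,
                              chip_base_count = 200,
                              chip_depth = 1e6,
                              chip_replicates = 2,
                              n_snp_probes = 10,
                              n_sex_probes = 10,
                              bin_size = 500,
                              seed = 1) {
  cfg <- as.list(environment())
  fr <- cfg$idmr_group_fractions
  if (!all(c("high", "intermediate", "low") %in% names(fr)) ||
      abs(sum(fr) - 1) > 1e-8 || any(fr < 0))
    stop("idmr_group_fractions must be named (high/intermediate/low),",
         " non-negative and sum to 1")
  for (f in c("planted_hypo_fraction", "shared_fraction",
              "resistant_fraction", "unstable_control_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  if (cfg$planted_effect < 0 || cfg$planted_effect >= 1)
    stop("planted_effect must be in [0, 1)")
  if (cfg$n_controls < 2) stop("need at least 2 controls")
  if (cfg$control_noise_sd <= 0) stop("control_noise_sd must be positive")
  structure(cfg, class = "sim_config")
}

# truncated additive Gaussian noise on the beta scale
add_noise <- function(x, sd) pmin(pmax(x + stats::rnorm(length(x), 0, sd), 0), 1)

#' Path of the bundled synthetic iDMR fixture
#'
#' A frozen 50-region iDMR catalogue with synthetic coordinates.  Region
#' names follow published human imprinted loci; coordinates and metadata
#' are fabricated so that 42 regions carry at least 3 simulated probes and
#' 8 carry fewer, matching the coverage structure the region filter is
#' designed for.
#'
#' @return file path of the BED-like TSV.
#' @export
idmr_fixture_path <- function() {
  system.file("extdata", "idmr50_synthetic.bed", package = "imprintscan",
              mustWork = TRUE)
}

# probes tiling a region: start+50, start+150, ... while < end
idmr_probe_positions <- function(start, end) {
  p <- seq(start + 50L, end - 1L, by = 100L)
  p[p < end]
}

#' Simulate a complete truth-annotated input bundle
#'
#' See [simulation_config()] for the generative model.  Background CpGs sit
#' two per 500 bp bin on chromosome `chrS1`; iDMR probes tile the bundled
#' region fixture at 100 bp spacing.  Per-CpG baselines are bimodal (low
#' mode ~0.10, high mode ~0.88); iDMR probes follow their region's group
#' level.  Planted hypomethylation (patients only) is arranged as
#' contiguous bin runs plus isolated bins, and as whole iDMRs drawn from
#' the high group.  Corrected clones redraw non-resistant planted loci from
#' the control distribution and keep resistant loci at patient level.
#'
#' @param config a [simulation_config()].
#' @return list of class `sim_bundle` with elements `beta`
#'   ([beta_matrix()]), `manifest` ([probe_manifest()]), `regions`
#'   ([region_set()]), `sheet` ([sample_sheet()]), `chip`
#'   ([chip_count_table()]), `truth` (list with `cpgs`, `bins`, `regions`
#'   data.frames) and `config`.
#' @export
simulate_bundle <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed, simulate_bundle_impl(config))
}

simulate_bundle_impl <- function(cfg) {
  bs <- as.integer(cfg$bin_size)
  n_bins <- max(2L, cfg$n_cpgs %/% 2L)

  # ---- background probes: two per bin on chrS1 -----------------------------
  bin_start <- (seq_len(n_bins) - 1L) * bs
  bg <- data.frame(
    probe_id = sprintf("cg%06d", seq_len(2L * n_bins)),
    chrom = "chrS1",
    pos = as.integer(rbind(bin_start + 100L, bin_start + 350L)),
    bin = rep(seq_len(n_bins), each = 2L),
    stringsAsFactors = FALSE)

  bin_mode_high <- stats::runif(n_bins) < 0.5
  bg_base_bin <- ifelse(bin_mode_high,
                        pmin(pmax(stats::rnorm(n_bins, 0.88, 0.03), 0.75), 0.97),
                        pmin(pmax(stats::rnorm(n_bins, 0.10, 0.03), 0.02), 0.25))
  bg$baseline <- pmin(pmax(
    bg_base_bin[bg$bin] + stats::rnorm(nrow(bg), 0, 0.01), 0.02), 0.98)

  # ---- iDMR regions and probes --------------------------------------------
  regions <- read_regions(idmr_fixture_path())
  if (cfg$n_idmrs < nrow(regions))
    regions <- region_set(as.data.frame(regions)[seq_len(cfg$n_idmrs), ])
  nr <- nrow(regions)
  fr <- cfg$idmr_group_fractions
  n_high <- round(fr[["high"]] * nr)
  n_int <- round(fr[["intermediate"]] * nr)
  grp <- c(rep("high", n_high), rep("intermediate", n_int),
           rep("low", nr - n_high - n_int))
  grp <- sample(grp)
  region_level <- ifelse(grp == "high", stats::runif(nr, 0.80, 0.92),
                         ifelse(grp == "intermediate",
                                stats::runif(nr, 0.45, 0.55),
                                stats::runif(nr, 0.15, 0.35)))

  id_probes <- do.call(rbind, lapply(seq_len(nr), function(i) {
    pos <- idmr_probe_positions(regions$start[i], regions$end[i])
    if (length(pos) == 0) return(NULL)
    data.frame(probe_id = sprintf("cg_%s_%02d", gsub("[^A-Za-z0-9]", "",
                                                     regions$name[i]),
                                  seq_along(pos)),
               chrom = regions$chrom[i], pos = as.integer(pos),
               region = regions$name[i],
               baseline = pmin(pmax(region_level[i] +
                                      stats::rnorm(length(pos), 0, 0.02),
                                    0.02), 0.98),
               stringsAsFactors = FALSE)
  }))
  region_n_probes <- stats::setNames(integer(nr), regions$name)
  tab <- table(id_probes$region)
  region_n_probes[names(tab)] <- as.integer(tab)

  # ---- flagged probes to exercise the probe filters ------------------------
  flag <- NULL
  if (cfg$n_snp_probes + cfg$n_sex_probes > 0) {
    flag <- data.frame(
      probe_id = c(sprintf("cg_snp%03d", seq_len(cfg$n_snp_probes)),
                   sprintf("cg_sex%03d", seq_len(cfg$n_sex_probes))),
      chrom = c(rep("chrS1", cfg$n_snp_probes),
                rep("chrX", cfg$n_sex_probes)),
      pos = as.integer(c(n_bins * bs + 100L +
                           100L * seq_len(cfg$n_snp_probes),
                         100L * seq_len(cfg$n_sex_probes))),
      snp = c(rep(TRUE, cfg$n_snp_probes), rep(FALSE, cfg$n_sex_probes)),
      sex = c(rep(FALSE, cfg$n_snp_probes), rep(TRUE, cfg$n_sex_probes)),
      baseline = stats::runif(cfg$n_snp_probes + cfg$n_sex_probes, 0.2, 0.8),
      stringsAsFactors = FALSE)
  }

  manifest <- probe_manifest(data.frame(
    probe_id = c(bg$probe_id, id_probes$probe_id,
                 if (!is.null(flag)) flag$probe_id),
    chrom = c(bg$chrom, id_probes$chrom, if (!is.null(flag)) flag$chrom),
    pos = c(bg$pos, id_probes$pos, if (!is.null(flag)) flag$pos),
    snp_overlap = c(rep(FALSE, nrow(bg) + nrow(id_probes)),
                    if (!is.null(flag)) flag$snp),
    sex_chrom = c(rep(FALSE, nrow(bg) + nrow(id_probes)),
                  if (!is.null(flag)) flag$sex),
    stringsAsFactors = FALSE))
  baseline <- stats::setNames(
    c(bg$baseline, id_probes$baseline, if (!is.null(flag)) flag$baseline),
    manifest$probe_id)

  # ---- plant hypomethylated loci ------------------------------------------
  # bins: carve runs (lengths cycling 3,2,1,2,1) out of maximal runs of
  # consecutive high-mode bins, separated by >= 1 unplanted bin so each
  # planted run is a maximal dm run.
  high_bins <- which(bin_mode_high)
  target_bins <- round(cfg$planted_hypo_fraction * length(high_bins))
  run_breaks <- c(TRUE, diff(high_bins) != 1L)
  seg_id <- cumsum(run_breaks)
  segments <- split(high_bins, seg_id)
  segments <- segments[sample.int(length(segments))]
  pattern <- c(3L, 2L, 1L, 2L, 1L)
  planted_runs <- list()
  planted_count <- 0L
  pi <- 1L
  for (seg in segments) {
    off <- 1L
    while (off <= length(seg) && planted_count < target_bins) {
      len <- min(pattern[((pi - 1L) %% length(pattern)) + 1L],
                 length(seg) - off + 1L,
                 target_bins - planted_count)
      planted_runs[[length(planted_runs) + 1L]] <- seg[off:(off + len - 1L)]
      planted_count <- planted_count + len
      pi <- pi + 1L
      off <- off + len + 1L           # >= 1 bin gap between runs
    }
    if (planted_count >= target_bins) break
  }

  # iDMRs: planted among high-group regions with >= 3 probes
  eligible_regions <- regions$name[grp == "high" &
                                     region_n_probes[regions$name] >= 3]
  n_plant_reg <- round(cfg$planted_hypo_fraction * length(eligible_regions))
  planted_regions <- eligible_regions[
    sample.int(length(eligible_regions), n_plant_reg)]

  # locus-level assignment: patient sharing and resistance
  loci <- c(lapply(planted_runs, function(r) list(kind = "run", bins = r)),
            lapply(planted_regions, function(nm) list(kind = "region",
                                                      name = nm)))
  n_loci <- length(loci)
  pat_names <- sprintf("pat%d", seq_len(cfg$n_patients))
  shared <- stats::runif(n_loci) < cfg$shared_fraction
  solo_patient <- pat_names[(seq_len(n_loci) - 1L) %% cfg$n_patients + 1L]
  resistant <- stats::runif(n_loci) < cfg$resistant_fraction

  # expand to per-probe planted annotation, per patient
  probe_bin <- stats::setNames(bg$bin, bg$probe_id)
  planted_probes <- stats::setNames(
    vector("list", cfg$n_patients), pat_names)
  for (p in pat_names) planted_probes[[p]] <- character(0)
  probe_resistant <- character(0)
  probe_locus_patient <- stats::setNames(character(0), character(0))
  truth_bins <- data.frame(bin = integer(0), run_id = integer(0),
                           run_length = integer(0), patients = character(0),
                           resistant = logical(0))
  truth_region_extra <- data.frame(name = character(0),
                                   patients = character(0),
                                   resistant = logical(0))
  for (i in seq_len(n_loci)) {
    loc <- loci[[i]]
    pats <- if (shared[i]) pat_names else solo_patient[i]
    if (loc$kind == "run") {
      pr <- bg$probe_id[bg$bin %in% loc$bins]
      truth_bins <- rbind(truth_bins, data.frame(
        bin = loc$bins, run_id = i, run_length = length(loc$bins),
        patients = paste(pats, collapse = ","), resistant = resistant[i]))
    } else {
      pr <- id_probes$probe_id[id_probes$region == loc$name]
      truth_region_extra <- rbind(truth_region_extra, data.frame(
        name = loc$name, patients = paste(pats, collapse = ","),
        resistant = resistant[i]))
    }
    for (p in pats) planted_probes[[p]] <- c(planted_probes[[p]], pr)
    if (resistant[i]) probe_resistant <- c(probe_resistant, pr)
    probe_locus_patient[pr] <- paste(pats, collapse = ",")
  }

  # ---- samples -------------------------------------------------------------
  np <- length(baseline)
  ctrl_ids <- sprintf("ctrl%02d", seq_len(cfg$n_controls))
  fib_ids <- if (cfg$n_fibroblast_controls > 0)
    sprintf("fib_ctrl%d", seq_len(cfg$n_fibroblast_controls)) else character(0)
  clone_ids <- unlist(lapply(pat_names, function(p)
    sprintf("%s_c%d", p, seq_len(cfg$clones_per_patient))))

  cols <- list()
  for (s in ctrl_ids) cols[[s]] <- add_noise(baseline, cfg$control_noise_sd)

  # unstable controls: a few iDMRs where one control drops by 0.3
  n_unstable <- round(cfg$unstable_control_fraction * nr)
  covered <- regions$name[region_n_probes[regions$name] > 0]
  unstable_regions <- if (n_unstable > 0)
    covered[sample.int(length(covered), min(n_unstable, length(covered)))]
  else character(0)
  for (nm in unstable_regions) {
    s <- sample(ctrl_ids, 1)
    pr <- id_probes$probe_id[id_probes$region == nm]
    cols[[s]][match(pr, manifest$probe_id)] <-
      pmax(cols[[s]][match(pr, manifest$probe_id)] - 0.3, 0)
  }

  fib_baseline <- baseline
  fib_baseline[id_probes$probe_id] <- cfg$fibroblast_idmr_level
  for (s in fib_ids) cols[[s]] <- add_noise(fib_baseline, cfg$control_noise_sd)

  pat_baseline <- list()
  for (p in pat_names) {
    pb <- baseline
    idx <- match(planted_probes[[p]], manifest$probe_id)
    pb[idx] <- pmax(pb[idx] - cfg$planted_effect, 0.02)
    pat_baseline[[p]] <- pb
    cols[[p]] <- add_noise(pb, cfg$control_noise_sd)
  }

  for (p in pat_names) {
    res_idx <- match(intersect(planted_probes[[p]], probe_resistant),
                     manifest$probe_id)
    for (k in seq_len(cfg$clones_per_patient)) {
      cb <- baseline                       # non-resistant loci recover
      cb[res_idx] <- pat_baseline[[p]][res_idx]
      cols[[sprintf("%s_c%d", p, k)]] <- add_noise(cb, cfg$control_noise_sd)
    }
  }

  beta <- beta_matrix(do.call(cbind, cols))
  rownames(beta) <- manifest$probe_id

  sheet <- sample_sheet(data.frame(
    sample_id = c(ctrl_ids, fib_ids, pat_names, clone_ids),
    role = c(rep("control", length(ctrl_ids) + length(fib_ids)),
             rep("patient", length(pat_names)),
             rep("corrected", length(clone_ids))),
    parent_patient = c(rep(NA, length(ctrl_ids) + length(fib_ids) +
                             length(pat_names)),
                       rep(pat_names, each = cfg$clones_per_patient)),
    cell_type = c(rep("iPSC", length(ctrl_ids)),
                  rep("fibroblast", length(fib_ids)),
                  rep("iPSC", length(pat_names) + length(clone_ids))),
    stringsAsFactors = FALSE))

  # ---- ChIP counts ---------------------------------------------------------
  planted_any <- unique(truth_region_extra$name)
  resistant_reg <- truth_region_extra$name[truth_region_extra$resistant]
  chip_rows <- list()
  for (cond in c("WT", "ICF1", "corrected")) {
    for (rep_i in seq_len(cfg$chip_replicates)) {
      fc_target <- rep(1, nr)
      if (cond == "ICF1")
        fc_target[regions$name %in% planted_any] <- cfg$chip_fc_at_hypo
      if (cond == "corrected")
        fc_target[regions$name %in% resistant_reg] <- cfg$chip_fc_at_hypo
      chip_rows[[length(chip_rows) + 1L]] <- data.frame(
        region = regions$name, condition = cond, replicate = rep_i,
        ip_count = stats::rpois(nr, cfg$chip_base_count * fc_target),
        input_count = stats::rpois(nr, cfg$chip_base_count),
        ip_depth = cfg$chip_depth, input_depth = cfg$chip_depth,
        stringsAsFactors = FALSE)
    }
  }
  chip <- chip_count_table(do.call(rbind, chip_rows))

  # ---- truth tables --------------------------------------------------------
  planted_all <- unique(unlist(planted_probes))
  truth_cpgs <- data.frame(
    probe_id = manifest$probe_id,
    baseline = unname(baseline),
    planted_status = ifelse(manifest$probe_id %in% planted_all, "hypo",
                            "null"),
    resistant = manifest$probe_id %in% probe_resistant,
    patients = unname(probe_locus_patient[manifest$probe_id]),
    stringsAsFactors = FALSE)
  truth_bins_full <- data.frame(
    bin_id = sprintf("chrS1:%d-%d", bin_start, bin_start + bs),
    chrom = "chrS1", start = bin_start,
    baseline_mode = ifelse(bin_mode_high, "high", "low"),
    planted = seq_len(n_bins) %in% truth_bins$bin,
    stringsAsFactors = FALSE)
  mb <- match(seq_len(n_bins), truth_bins$bin)
  truth_bins_full$run_id <- truth_bins$run_id[mb]
  truth_bins_full$run_length <- truth_bins$run_length[mb]
  truth_bins_full$patients <- truth_bins$patients[mb]
  truth_bins_full$resistant <- truth_bins$resistant[mb]
  truth_regions <- data.frame(
    name = regions$name, group = grp, n_probes = unname(region_n_probes),
    planted = regions$name %in% planted_any,
    resistant = regions$name %in% resistant_reg,
    patients = truth_region_extra$patients[
      match(regions$name, truth_region_extra$name)],
    unstable = regions$name %in% unstable_regions,
    stringsAsFactors = FALSE)

  structure(list(beta = beta, manifest = manifest, regions = regions,
                 sheet = sheet, chip = chip,
                 truth = list(cpgs = truth_cpgs, bins = truth_bins_full,
                              regions = truth_regions),
                 config = cfg),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("sim_bundle: %d probes x %d samples, %d iDMRs, %d planted CpGs\n",
              nrow(x$beta), ncol(x$beta), nrow(x$regions),
              sum(x$truth$cpgs$planted_status != "null")))
  invisible(x)
}

#' Write a simulated bundle to disk
#'
#' Emits the io-layer formats (`beta.tsv`, `manifest.tsv`, `regions.bed`,
#' `samples.tsv`, `chip_counts.tsv`) plus truth tables
#' (`truth_cpgs.tsv`, `truth_bins.tsv`, `truth_regions.tsv`) and the
#' configuration (`config.json`).  Files round-trip through the package
#' readers.
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(bundle$beta, file.path(dir, "beta.tsv"),
                    id_col = "probe_id")
  write_manifest(bundle$manifest, file.path(dir, "manifest.tsv"))
  write_regions(bundle$regions, file.path(dir, "regions.bed"))
  write_sample_sheet(bundle$sheet, file.path(dir, "samples.tsv"))
  write_chip_counts(bundle$chip, file.path(dir, "chip_counts.tsv"))
  for (nm in names(bundle$truth))
    utils::write.table(bundle$truth[[nm]],
                       file.path(dir, sprintf("truth_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(bundle$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param dir directory containing the bundle files.
#' @return list with `beta`, `manifest`, `regions`, `sheet`, `chip` (and
#'   `truth` when the truth tables are present).
#' @export
read_bundle <- function(dir) {
  out <- list(
    beta = read_beta_matrix(file.path(dir, "beta.tsv")),
    manifest = read_manifest(file.path(dir, "manifest.tsv")),
    regions = read_regions(file.path(dir, "regions.bed")),
    sheet = read_sample_sheet(file.path(dir, "samples.tsv")),
    chip = read_chip_counts(file.path(dir, "chip_counts.tsv")))
  tf <- file.path(dir, c("truth_cpgs.tsv", "truth_bins.tsv",
                         "truth_regions.tsv"))
  if (all(file.exists(tf)))
    out$truth <- list(cpgs = utils::read.delim(tf[1]),
                      bins = utils::read.delim(tf[2]),
                      regions = utils::read.delim(tf[3]))
  out
}
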