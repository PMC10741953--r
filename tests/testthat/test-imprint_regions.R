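# Manifest whose probes tile the bundled 50-region fixture at 100 bp
# spacing (the synthetic generator's layout): 42 regions gain >= 3 probes.
fixture_manifest <- function() {
  regions <- read_regions(idmr_fixture_path())
  rows <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    pos <- seq(regions$start[i] + 50L, regions$end[i] - 1L, by = 100L)
    data.frame(probe_id = sprintf("cg_%02d_%02d", i, seq_along(pos)),
               chrom = regions$chrom[i], pos = pos,
               snp_overlap = FALSE, sex_chrom = FALSE)
  }))
  probe_manifest(rows)
}

test_that("region coverage filter reproduces the 50 -> 42 -> 41 cascade", {
  regions <- read_regions(idmr_fixture_path())
  man <- fixture_manifest()
  kept <- filter_idmr_regions(regions, man, min_probes = 3)
  expect_equal(nrow(kept), 42L)
  kept41 <- filter_idmr_regions(regions, man, min_probes = 3,
                                exclude = "VTRNA2")
  expect_equal(nrow(kept41), 41L)
  expect_false("VTRNA2" %in% kept41$name)

  # idempotent; identity under min_probes = 1; order preserved
  again <- suppressWarnings(filter_idmr_regions(kept41, man, min_probes = 3,
                                                exclude = "VTRNA2"))
  expect_equal(as.data.frame(again), as.data.frame(kept41),
               ignore_attr = TRUE)
  expect_equal(nrow(filter_idmr_regions(regions, man, min_probes = 1)), 50L)
  expect_equal(kept41$name, intersect(regions$name, kept41$name))
  expect_warning(filter_idmr_regions(regions, man, exclude = "NOT_A_DMR"),
                 "not present")
})

test_that("control-level grouping uses the >=0.60 / [0.40,0.60) / <0.40
           partition and is total", {
  sheet <- tiny_sheet(n_controls = 2)
  mk <- function(v) tiny_beta(matrix(rep(v, each = 2), ncol = 2,
                                     byrow = TRUE),
                              units = sprintf("r%d", seq_along(v)),
                              samples = c("ctrl01", "ctrl02"))
  g <- classify_region_groups(mk(c(0.75, 0.45, 0.30, 0.60, 0.40,
                                   0.5999, 0.3999)), sheet)
  expect_equal(g$group, c("high", "intermediate", "low", "high",
                          "intermediate", "intermediate", "low"))
  expect_true(all(g$group %in% c("high", "intermediate", "low")))
  expect_equal(nrow(g), 7L)
})

test_that("region-level calling reuses the bin statistic per sample", {
  sheet <- tiny_sheet(n_controls = 5, n_patients = 2)
  ctrl <- c(0.84, 0.85, 0.85, 0.86, 0.87)
  vals <- rbind(sev  = c(ctrl, 0.30, 0.30),   # hypo in both patients
                mild = c(ctrl, 0.70, 0.87),   # within 0.2: unchanged
                one  = c(ctrl, 0.30, 0.86))   # hypo in pat1 only
  b <- tiny_beta(vals, samples = c(sprintf("ctrl%02d", 1:5), "pat1", "pat2"))
  res <- call_region_dm(b, sheet)
  calls <- res$calls
  get <- function(u, s) calls$status[calls$unit_id == u & calls$sample_id == s]
  expect_equal(get("sev", "pat1"), "hypo")
  expect_equal(get("sev", "pat2"), "hypo")
  expect_equal(get("mild", "pat1"), "unchanged")
  expect_equal(get("one", "pat1"), "hypo")
  expect_equal(get("one", "pat2"), "unchanged")
})

test_that("recovery follows |corrected delta beta| < 0.2, strictly", {
  sheet <- tiny_sheet(n_controls = 2, n_patients = 1, clones_per_patient = 3)
  ref <- structure(data.frame(unit_id = c("r1", "r2", "r3"),
                              mean_m = 0, sd_m = 0.1,
                              median_beta = c(0.8, 0.8, 0.8),
                              n_controls = 2L),
                   class = c("control_reference", "data.frame"))
  patient_calls <- structure(data.frame(
    unit_id = c("r1", "r2", "r3"), sample_id = "pat1",
    delta_m = -3, delta_beta = -0.45, sd_m = 0.1,
    status = c("hypo", "hypo", "unchanged")),
    class = c("dm_calls", "data.frame"))
  cb <- tiny_beta(rbind(r1 = c(0.75, 0.55, 0.60),
                        r2 = c(0.35, 0.95, 0.60),
                        r3 = c(0.80, 0.80, 0.80)),
                  samples = c("pat1_c1", "pat1_c2", "pat1_c3"))
  rec <- classify_recovery(patient_calls, cb, ref, sheet)
  # only dm units enter; r3 (unchanged) does not
  expect_setequal(unique(rec$unit_id), c("r1", "r2"))
  pick <- function(u, cl) rec$recovered[rec$unit_id == u &
                                          rec$corrected_id == cl]
  expect_true(pick("r1", "pat1_c1"))    # |0.75-0.8| = 0.05
  expect_false(pick("r1", "pat1_c2"))   # |0.55-0.8| = 0.25
  expect_false(pick("r2", "pat1_c1"))   # |0.35-0.8| = 0.45
  expect_true(pick("r2", "pat1_c2"))    # |0.95-0.8| = 0.15
  # exact boundary |delta| == 0.2 is NOT recovered (strict <)
  expect_false(pick("r1", "pat1_c3"))   # |0.60-0.8| = 0.2
})

test_that("recovery_summary computes per-clone, per-class and shared
           percentages", {
  rec <- structure(data.frame(
    unit_id = rep(c("u1", "u2", "u3", "u4", "u5"), times = 2),
    patient_id = "pat1",
    corrected_id = rep(c("c1", "c2"), each = 5),
    patient_status = "hypo",
    corrected_delta_beta = 0,
    recovered = c(TRUE, TRUE, TRUE, TRUE, FALSE,
                  TRUE, TRUE, FALSE, FALSE, FALSE)),
    class = c("recovery_calls", "data.frame"))
  s <- recovery_summary(rec)
  expect_equal(s$per_clone$pct_recovered[s$per_clone$corrected_id == "c1"],
               80)
  expect_equal(s$per_clone$pct_recovered[s$per_clone$corrected_id == "c2"],
               40)
  # shared units: all five seen for the single patient; recovered in ALL
  # clones: u1, u2
  expect_equal(s$shared$n_shared, 5L)
  expect_equal(s$shared$n_recovered_all, 2L)

  grouping <- c(u1 = "island", u2 = "island", u3 = "shore", u4 = "shore")
  s2 <- recovery_summary(rec, grouping)
  isl_c1 <- s2$per_class[s2$per_class$corrected_id == "c1" &
                           s2$per_class$class == "island", ]
  expect_equal(isl_c1$pct_recovered, 100)
  expect_true("(unclassified)" %in% s2$per_class$class)
  expect_error(recovery_summary(rec[0, ]), "no recovery calls")
})

test_that("recovery is monotone in |corrected delta beta|", {
  sheet <- tiny_sheet(n_controls = 2, n_patients = 1, clones_per_patient = 1)
  ref <- structure(data.frame(unit_id = "r1", mean_m = 0, sd_m = 0.1,
                              median_beta = 0.8, n_controls = 2L),
                   class = c("control_reference", "data.frame"))
  patient_calls <- structure(data.frame(
    unit_id = "r1", sample_id = "pat1", delta_m = -3, delta_beta = -0.45,
    sd_m = 0.1, status = "hypo"), class = c("dm_calls", "data.frame"))
  deltas <- seq(0, 0.5, by = 0.025)
  rec <- vapply(deltas, function(d) {
    cb <- tiny_beta(rbind(r1 = 0.8 - d), samples = "pat1_c1")
    classify_recovery(patient_calls, cb, ref, sheet)$recovered
  }, logical(1))
  expect_false(any(diff(rec) == 1))  # never flips FALSE -> TRUE as d grows
})

test_that("planted resistant/recoverable labels are recovered with >= 95%
           accuracy at effect 0.4 and control SD 0.02", {
  set.seed(101)
  n_units <- 200
  n_clones <- 4
  sheet <- tiny_sheet(n_controls = 11, n_patients = 1,
                      clones_per_patient = n_clones)
  base <- runif(n_units, 0.75, 0.95)
  resistant <- runif(n_units) < 0.4
  ctrl <- sapply(sprintf("ctrl%02d", 1:11), function(s)
    pmin(pmax(base + rnorm(n_units, 0, 0.02), 0), 1))
  pat <- pmin(pmax(base - 0.4 + rnorm(n_units, 0, 0.02), 0), 1)
  clones <- sapply(seq_len(n_clones), function(k)
    ifelse(resistant,
           pmin(pmax(base - 0.4 + rnorm(n_units, 0, 0.02), 0), 1),
           pmin(pmax(base + rnorm(n_units, 0, 0.02), 0), 1)))
  colnames(clones) <- sprintf("pat1_c%d", seq_len(n_clones))
  vals <- cbind(ctrl, pat1 = pat, clones)
  rownames(vals) <- sprintf("u%03d", seq_len(n_units))
  b <- beta_matrix(vals)
  m <- beta_to_m(b)
  ref <- build_reference(b, m, sheet)
  pat_calls <- call_dm(b, m, ref, "pat1")
  expect_gte(mean(pat_calls$status == "hypo"), 0.95)
  rec <- classify_recovery(pat_calls, b, ref, sheet)
  # planted truth: resistant -> not recovered in any clone
  truth <- !resistant[match(rec$unit_id, rownames(vals))]
  expect_gte(mean(rec$recovered == truth), 0.95)
})
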