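test_that("build_reference computes mean/sd of control M and median beta", {
  sheet <- tiny_sheet(n_controls = 3, n_patients = 1)
  b <- tiny_beta(cbind(ctrl01 = c(0.3, 0.6), ctrl02 = c(0.5, 0.6),
                       ctrl03 = c(0.9, 0.6), pat1 = c(0.5, 0.9)),
                 units = c("u1", "u2"))
  # use a hand-built M matrix so the arithmetic is transparent
  mvals <- cbind(ctrl01 = c(1, 0), ctrl02 = c(2, 0),
                 ctrl03 = c(3, 0), pat1 = c(0, 0))
  rownames(mvals) <- rownames(b)
  m <- m_matrix(mvals)
  ref <- build_reference(b, m, sheet)
  expect_equal(ref$mean_m, c(2, 0))
  expect_equal(ref$sd_m, c(1, 0))          # n-1 denominator
  expect_equal(ref$median_beta, c(0.5, 0.6))
  expect_equal(ref$n_controls, c(3L, 3L))

  # units missing in a control are dropped with a warning
  b_na <- unclass(b); b_na["u2", "ctrl02"] <- NA
  expect_warning(ref2 <- build_reference(beta_matrix(b_na), m, sheet),
                 "dropped")
  expect_equal(ref2$unit_id, "u1")
  expect_error(build_reference(b, m, suppressWarnings(tiny_sheet(n_controls = 1)),
                               cell_type = NULL), ">= 2 control")
})

test_that("call_dm applies both criteria with strict inequalities", {
  ref <- structure(data.frame(unit_id = c("u1", "u2", "u3"), mean_m = 0,
                              sd_m = 0.2, median_beta = 0.5,
                              n_controls = 3L),
                   class = c("control_reference", "data.frame"))
  b <- tiny_beta(rbind(u1 = 0.8, u2 = 0.65, u3 = 0.5), samples = "s")
  m <- m_matrix(matrix(c(1, 1, 0), 3, 1,
                       dimnames = list(c("u1", "u2", "u3"), "s")))
  calls <- call_dm(b, m, ref, "s")
  expect_equal(calls$status, c("hyper", "unchanged", "unchanged"))
  expect_equal(calls$delta_m, c(1, 1, 0))
  expect_equal(calls$delta_beta, c(0.3, 0.15, 0))
  expect_error(call_dm(b, m, ref, "nope"), "unknown sample")

  # boundary: delta_beta exactly 0.2 or |dM| exactly k*sd is NOT called
  b2 <- tiny_beta(rbind(u1 = 0.7), samples = "s")
  m2 <- m_matrix(matrix(0.6, 1, 1, dimnames = list("u1", "s")))
  expect_equal(call_dm(b2, m2, ref[1, ], "s")$status, "unchanged")
})

test_that("sd_m = 0 units fall back to the beta criterion with a warning", {
  ref <- structure(data.frame(unit_id = "u1", mean_m = 2, sd_m = 0,
                              median_beta = 0.8, n_controls = 3L),
                   class = c("control_reference", "data.frame"))
  b <- tiny_beta(rbind(u1 = 0.3), samples = "s")
  m <- beta_to_m(b)
  expect_warning(calls <- call_dm(b, m, ref, "s"), "sd_m = 0")
  expect_equal(calls$status, "hypo")
  expect_equal(attr(calls, "n_sd_zero"), 1L)
})

test_that("assign_bins floors positions into half-open 500 bp tiles", {
  man <- probe_manifest(data.frame(
    probe_id = c("a", "b", "c"), chrom = "chr1",
    pos = c(1250L, 1500L, 0L), snp_overlap = FALSE, sex_chrom = FALSE))
  bins <- assign_bins(man)
  expect_equal(bins$bin_start, c(1000L, 1500L, 0L))
  expect_equal(bins$bin_id[2], "chr1:1500-2000")
  expect_equal(parse_bin_ids(bins$bin_id)$end, bins$bin_start + 500L)
})

test_that("aggregate_units averages members and enforces min_cpgs and
           per-sample completeness", {
  b <- tiny_beta(rbind(p1 = c(0.2, 0.1), p2 = c(0.4, NA), p3 = c(0.6, 0.3),
                       p4 = c(0.5, 0.5)),
                 samples = c("s1", "s2"))
  membership <- c(p1 = "g1", p2 = "g1", p3 = "g1", p4 = "g2")
  agg <- aggregate_units(b, membership, min_cpgs = 2)
  expect_equal(rownames(agg), "g1")          # g2 has 1 member: excluded
  expect_equal(unname(agg["g1", "s1"]), 0.4) # mean(0.2, 0.4, 0.6)
  expect_true(is.na(agg["g1", "s2"]))        # p2 missing in s2
  agg3 <- aggregate_units(b, membership, min_cpgs = 3)
  expect_equal(rownames(agg3), "g1")
  expect_equal(nrow(aggregate_units(b, c(p4 = "g2"), min_cpgs = 3)), 0L)
  expect_error(aggregate_units(b, character(0)), "empty membership")
})

test_that("find_clusters matches the exhaustive run-enumeration oracle", {
  # spec worked examples
  cs <- find_clusters(data.frame(chrom = "c", start = c(1000, 1500, 3000)))
  expect_equal(length(cs$clusters), 1L)
  expect_equal(cs$clusters[[1]]$start, c(1000, 1500))
  expect_equal(cs$isolated$start, 3000)
  cs1 <- find_clusters(data.frame(chrom = "c", start = 500))
  expect_equal(length(cs1$clusters), 0L)
  expect_equal(nrow(cs1$isolated), 1L)
  cs3 <- find_clusters(data.frame(chrom = "c", start = c(0, 500, 1000)))
  expect_equal(length(cs3$clusters), 1L)
  expect_equal(nrow(cs3$isolated), 0L)

  # property: all subsets of 10 candidate bins, plus cross-chromosome cases
  starts_all <- (0:9) * 500
  for (mask in 1:1023) {
    starts <- starts_all[as.logical(bitwAnd(mask, 2^(0:9)))]
    got <- find_clusters(data.frame(chrom = "c", start = starts))
    want <- oracle_clusters(starts, rep("c", length(starts)))
    expect_equal(lapply(got$clusters, function(d) d$start), want$clusters)
    expect_equal(sort(got$isolated$start), want$isolated)
  }
  # chromosome change breaks contiguity even with adjacent coordinates
  mixed <- data.frame(chrom = c("c1", "c2"), start = c(0, 500))
  expect_equal(length(find_clusters(mixed)$clusters), 0L)
})

test_that("mirror symmetry: beta -> 1-beta swaps hyper and hypo exactly", {
  set.seed(11)
  sheet <- tiny_sheet(n_controls = 5, n_patients = 1)
  vals <- matrix(runif(300 * 6, 0.05, 0.95), 300, 6)
  colnames(vals) <- c(sprintf("ctrl%02d", 1:5), "pat1")
  rownames(vals) <- sprintf("u%03d", 1:300)
  # inject real effects so both labels occur
  vals[1:30, "pat1"] <- pmin(vals[1:30, "pat1"] + 0.5, 0.99)
  vals[31:60, "pat1"] <- pmax(vals[31:60, "pat1"] - 0.5, 0.01)
  b <- beta_matrix(vals)
  m <- beta_to_m(b)
  ref <- build_reference(b, m, sheet)
  calls <- call_dm(b, m, ref, "pat1")

  b_mirror <- beta_matrix(1 - vals)
  m_mirror <- beta_to_m(b_mirror)
  ref_m <- build_reference(b_mirror, m_mirror, sheet)
  calls_m <- call_dm(b_mirror, m_mirror, ref_m, "pat1")

  swap <- c(hyper = "hypo", hypo = "hyper", unchanged = "unchanged")
  expect_gt(sum(calls$status == "hyper"), 0)
  expect_gt(sum(calls$status == "hypo"), 0)
  expect_identical(calls_m$status, unname(swap[calls$status]))
})

test_that("a sample equal to a control yields zero calls wherever sd_m > 0", {
  set.seed(13)
  sheet <- tiny_sheet(n_controls = 6, n_patients = 1)
  vals <- matrix(runif(200 * 7, 0.02, 0.98), 200, 7)
  colnames(vals) <- c(sprintf("ctrl%02d", 1:6), "pat1")
  vals[, "pat1"] <- vals[, "ctrl01"]
  rownames(vals) <- sprintf("u%03d", 1:200)
  b <- beta_matrix(vals)
  m <- beta_to_m(b)
  ref <- build_reference(b, m, sheet)
  calls <- call_dm(b, m, ref, "pat1")
  expect_true(all(calls$status[ref$sd_m > 0] == "unchanged"))
})

test_that("raising a sample's beta above the control median never demotes a
           hyper call", {
  sheet <- tiny_sheet(n_controls = 5, n_patients = 1)
  ctrl <- c(0.30, 0.32, 0.34, 0.36, 0.38)
  grid <- seq(0.40, 0.98, by = 0.02)
  vals <- cbind(matrix(rep(ctrl, each = length(grid)), ncol = 5,
                       byrow = FALSE), grid)
  # one unit per grid point: same reference, increasing sample beta
  statuses <- vapply(grid, function(g) {
    v <- matrix(c(ctrl, g), 1, 6,
                dimnames = list("u", c(sprintf("ctrl%02d", 1:5), "pat1")))
    b <- beta_matrix(v)
    m <- beta_to_m(b)
    call_dm(b, m, build_reference(b, m, sheet), "pat1")$status
  }, character(1))
  # once hyper, always hyper as beta increases
  first_hyper <- match("hyper", statuses)
  expect_false(is.na(first_hyper))
  expect_true(all(statuses[first_hyper:length(statuses)] == "hyper"))
})

test_that("bin-level calling equals calling on a hand-built bin matrix", {
  sheet <- tiny_sheet(n_controls = 3, n_patients = 1)
  man <- probe_manifest(data.frame(
    probe_id = sprintf("p%d", 1:6), chrom = "chr1",
    pos = c(0L, 100L, 200L, 500L, 600L, 700L),
    snp_overlap = FALSE, sex_chrom = FALSE))
  set.seed(5)
  vals <- matrix(runif(6 * 4, 0.3, 0.9), 6, 4,
                 dimnames = list(sprintf("p%d", 1:6),
                                 c(sprintf("ctrl%02d", 1:3), "pat1")))
  vals[4:6, "pat1"] <- vals[4:6, "pat1"] - 0.29
  b <- beta_matrix(vals)
  res <- call_bins(b, man, sheet, sample_ids = "pat1")

  hand <- rbind("chr1:0-500" = colMeans(vals[1:3, ]),
                "chr1:500-1000" = colMeans(vals[4:6, ]))
  hb <- beta_matrix(hand)
  hm <- beta_to_m(hb)
  hand_calls <- call_dm(hb, hm, build_reference(hb, hm, sheet), "pat1")
  expect_equal(as.data.frame(res$calls), as.data.frame(hand_calls))
})
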