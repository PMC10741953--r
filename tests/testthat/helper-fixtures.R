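# Shared fixtures and independent oracles for the test suite.  The oracles
# are deliberately naive (per-element loops, full enumeration) and never
# call the vectorised implementation they check.

tiny_beta <- function(values, units = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(units))
    units <- if (!is.null(rownames(m))) rownames(m)
    else sprintf("u%d", seq_len(nrow(m)))
  if (is.null(samples))
    samples <- if (!is.null(colnames(m))) colnames(m)
    else sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(units, samples)
  beta_matrix(m)
}

tiny_sheet <- function(n_controls = 3, n_patients = 1,
                       clones_per_patient = 0, cell_type = "iPSC") {
  ctrl <- sprintf("ctrl%02d", seq_len(n_controls))
  pats <- if (n_patients > 0) sprintf("pat%d", seq_len(n_patients))
  else character(0)
  clones <- unlist(lapply(pats, function(p)
    if (clones_per_patient > 0)
      sprintf("%s_c%d", p, seq_len(clones_per_patient)) else character(0)))
  sample_sheet(data.frame(
    sample_id = c(ctrl, pats, clones),
    role = c(rep("control", n_controls), rep("patient", n_patients),
             rep("corrected", length(clones))),
    parent_patient = c(rep(NA, n_controls + n_patients),
                       rep(pats, each = clones_per_patient)),
    cell_type = cell_type,
    stringsAsFactors = FALSE))
}

write_tsv_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# ---- oracle: direct per-unit differential methylation calling -------------
# Plain loops, scalar arithmetic, no vectorisation; mirrors the definition:
# controls -> mean/sd of M (n-1 denominator), median of beta; call when
# |M_s - mean_m| > k*sd_m (or sd_m == 0 and |dM| > 0) AND |dbeta| > delta.
oracle_call_dm <- function(beta_mat, sample_id, control_cols, k = 3,
                           delta = 0.2, eps = 0.001) {
  m_of <- function(b) {
    b <- min(max(b, eps), 1 - eps)
    log2(b / (1 - b))
  }
  out <- character(nrow(beta_mat))
  names(out) <- rownames(beta_mat)
  for (u in rownames(beta_mat)) {
    cb <- as.numeric(beta_mat[u, control_cols])
    cm <- vapply(cb, m_of, numeric(1))
    mu <- sum(cm) / length(cm)
    sdm <- sqrt(sum((cm - mu)^2) / (length(cm) - 1))
    medb <- stats::median(cb)
    bs <- beta_mat[u, sample_id]
    dm <- m_of(bs) - mu
    db <- bs - medb
    pass_m <- if (sdm == 0) abs(dm) > 0 else abs(dm) > k * sdm
    out[u] <- if (pass_m && db > delta) "hyper"
    else if (pass_m && db < -delta) "hypo" else "unchanged"
  }
  out
}

# ---- oracle: exhaustive run enumeration for cluster detection -------------
# O(n^2): a run [i..j] is maximal iff all consecutive pairs are adjacent and
# neither i-1 nor j+1 extends it.
oracle_clusters <- function(starts, chroms, min_bins = 2, bin_size = 500) {
  ord <- order(chroms, starts)
  starts <- starts[ord]; chroms <- chroms[ord]
  n <- length(starts)
  adj <- function(i, j) chroms[i] == chroms[j] &&
    starts[j] == starts[i] + bin_size
  clusters <- list(); isolated <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      run_ok <- all(vapply(seq_len(max(0, j - i)), function(t)
        adj(i + t - 1, i + t), logical(1)))
      maximal <- run_ok &&
        (i == 1 || !adj(i - 1, i)) && (j == n || !adj(j, j + 1))
      if (maximal) {
        if (j - i + 1 >= min_bins)
          clusters[[length(clusters) + 1]] <- starts[i:j]
        else for (t in i:j) isolated[[length(isolated) + 1]] <- starts[t]
      }
    }
  }
  list(clusters = clusters,
       isolated = if (length(isolated) == 0) numeric(0)
       else sort(unlist(isolated)))
}

# ---- oracle: exact Wilcoxon signed-rank by sign enumeration ---------------
# One-sided P(W+ >= observed) over all 2^n sign assignments of tie-free |d|.
oracle_signed_rank_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  switch(alternative,
         greater = mean(w_all >= w_obs),
         less = mean(w_all <= w_obs),
         two.sided = min(1, 2 * min(mean(w_all >= w_obs),
                                    mean(w_all <= w_obs))))
}

# ---- oracle: exact two-sample rank-sum by full enumeration ----------------
# Two-sided p over all choose(n1+n2, n1) assignments of the pooled ranks.
oracle_rank_sum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(n1 + n2, n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# ---- oracle: Benjamini-Hochberg step-up by its textbook definition --------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  # step-up: cumulative minimum from the largest rank down
  for (i in seq_len(m)) adj[i] <- min(sorted[i:m], 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
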