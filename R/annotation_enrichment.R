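# ---------------------------------------------------------------------------
# Genomic-element annotation, permutation (shuffle) overlap test, ChIP-seq
# IP/input fold change, and the Wilcoxon/BH statistics used to compare
# enrichment and methylation differences.
# ---------------------------------------------------------------------------

#' Annotate units with genomic-element classes
#'
#' Multi-label containment annotation: a unit is tagged with every class
#' whose intervals contain it.  Units covered by no class get an empty
#' label set (supply an explicit "intergenic" class if the complement
#' should be labelled).
#'
#' @param units data.frame with either point positions (`unit_id`, `chrom`,
#'   `pos`) or intervals (`unit_id`/`name`, `chrom`, `start`, `end`); an
#'   interval is tagged when it overlaps a class interval.
#' @param classes named list of [region_set()]s, one per annotation class
#'   (exon, intron, promoter, CpG island, LINE, ...).
#' @return named list mapping unit id -> character vector of class names.
#' @export
annotate_units <- function(units, classes) {
  if (is.null(names(classes)) || any(names(classes) == ""))
    stop("classes must be a named list of region sets")
  if (anyDuplicated(names(classes))) stop("duplicate class names")
  id_col <- if ("unit_id" %in% names(units)) "unit_id" else "name"
  point <- "pos" %in% names(units)
  out <- stats::setNames(
    rep(list(character(0)), nrow(units)), units[[id_col]])
  for (cls in names(classes)) {
    iv <- classes[[cls]]
    for (j in seq_len(nrow(iv))) {
      hit <- if (point) {
        units$chrom == iv$chrom[j] &
          units$pos >= iv$start[j] & units$pos < iv$end[j]
      } else {
        units$chrom == iv$chrom[j] &
          units$start < iv$end[j] & units$end > iv$start[j]
      }
      for (i in which(hit))
        out[[i]] <- union(out[[i]], cls)
    }
  }
  out
}

#' Permutation (shuffle) test for the overlap of two unit sets
#'
#' Tests whether two sets of units drawn from a common universe (e.g.
#' differentially methylated CpGs of two patients among all analysed CpGs)
#' overlap more than expected by chance.  Each permutation redraws a
#' uniform random subset of size |A| from the universe and counts its
#' overlap with B; the one-sided p-value is `(b + 1) / (n_perm + 1)` where
#' `b` is the number of permutations with overlap >= observed.
#'
#' @param set_a,set_b character vectors of unit ids, subsets of `universe`.
#' @param universe character vector of all eligible unit ids.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for reproducibility.
#' @return list of class `overlap_test` with `observed_overlap`, `n_perm`,
#'   `p_value`, `null_mean` (mean permuted overlap; the hypergeometric
#'   expectation |A||B|/|U| in the limit).
#' @export
shuffle_overlap_test <- function(set_a, set_b, universe, n_perm = 9999,
                                 seed = 1) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (length(setdiff(set_a, universe)) > 0 ||
      length(setdiff(set_b, universe)) > 0)
    stop("set_a and set_b must be subsets of the universe")
  if (n_perm < 1) stop("n_perm must be >= 1")
  observed <- length(intersect(set_a, set_b))
  in_b <- universe %in% set_b
  nA <- length(set_a)
  nU <- length(universe)
  perm_overlap <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      sum(in_b[sample.int(nU, nA)]), integer(1))
  })
  b <- sum(perm_overlap >= observed)
  structure(list(observed_overlap = observed, n_perm = as.integer(n_perm),
                 p_value = (b + 1) / (n_perm + 1),
                 null_mean = mean(perm_overlap)),
            class = "overlap_test")
}

# Evaluate an expression under a local RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("shuffle overlap test: observed %d, null mean %.2f, p = %g (%d permutations)\n",
              x$observed_overlap, x$null_mean, x$p_value, x$n_perm))
  invisible(x)
}

#' ChIP-seq IP/input fold change
#'
#' `FC = (ip_count / ip_depth) / (input_count / input_depth)` per (region,
#' condition, replicate).  Records with `input_count == 0` get a
#' pseudocount of 0.5 added to both IP and input counts and are flagged in
#' the `pseudocount` column.
#'
#' @param counts a [chip_count_table()].
#' @return the table with added columns `fc` and `pseudocount`.
#' @export
chip_fold_change <- function(counts) {
  out <- as.data.frame(counts)
  pseudo <- out$input_count == 0
  ip <- out$ip_count + ifelse(pseudo, 0.5, 0)
  inp <- out$input_count + ifelse(pseudo, 0.5, 0)
  out$fc <- (ip / out$ip_depth) / (inp / out$input_depth)
  out$pseudocount <- pseudo
  out
}

#' Paired one-sided Wilcoxon comparisons of per-region enrichment
#'
#' For each requested comparison of two conditions over a matched region
#' set, computes paired differences (a - b), a one-sided Wilcoxon
#' signed-rank p-value (exact when there are no ties or zeros, otherwise a
#' tie-corrected normal approximation), the paired rank-biserial effect
#' size `r = (W+ - W-) / (W+ + W-)`, and BH-adjusted q-values across all
#' comparisons requested in the call (one family per call).
#'
#' Zero differences are dropped before ranking (standard signed-rank
#' convention).
#'
#' @param fc numeric matrix of fold changes, regions x conditions (a
#'   replicate-averaged condition summary), or a data.frame from
#'   [chip_fold_change()] which is then averaged over replicates.
#' @param comparisons list of lists/character vectors `c(a, b)` naming the
#'   condition columns to compare; paired as a - b.
#' @param alternative one-sided direction, `"greater"` (differences tend
#'   positive) or `"less"`; recycled across comparisons.
#' @return data.frame with columns `comparison`, `a`, `b`, `n`,
#'   `median_diff`, `p_value`, `q_value`, `rank_biserial`.
#' @export
enrichment_compare <- function(fc, comparisons, alternative = "greater") {
  if (is.data.frame(fc)) {
    if (!all(c("region", "condition", "fc") %in% names(fc)))
      stop("fc data.frame must have columns region, condition, fc")
    fc <- stats::xtabs(fc ~ region + condition,
                       data = stats::aggregate(fc ~ region + condition,
                                               data = fc, FUN = mean))
    fc <- as.matrix(unclass(fc))
  }
  if (length(comparisons) == 0) stop("no comparisons requested")
  alternative <- rep_len(alternative, length(comparisons))
  rows <- lapply(seq_along(comparisons), function(i) {
    cmp <- comparisons[[i]]
    a <- cmp[[1]]; b <- cmp[[2]]
    if (!all(c(a, b) %in% colnames(fc)))
      stop("unknown condition in comparison: ", a, " vs ", b)
    keep <- stats::complete.cases(fc[, c(a, b), drop = FALSE])
    d <- fc[keep, a] - fc[keep, b]
    if (length(d) < 2) stop("fewer than 2 paired regions for ", a, " vs ", b)
    data.frame(comparison = paste0(a, "-", b), a = a, b = b,
               n = length(d), median_diff = stats::median(d),
               p_value = wilcoxon_signed_rank(d, alternative[i]),
               rank_biserial = rank_biserial_paired(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[, c("comparison", "a", "b", "n", "median_diff", "p_value",
                 "q_value", "rank_biserial")]
  rownames(out) <- NULL
  out
}

#' One-sample / paired Wilcoxon signed-rank p-value
#'
#' Exact when the non-zero differences are tie-free, otherwise a
#' tie-corrected normal approximation with continuity correction (the
#' behaviour of [stats::wilcox.test()]).  Zero differences are dropped.
#'
#' @param d numeric vector of paired differences.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return p-value; 1 when every difference is zero.
#' @export
wilcoxon_signed_rank <- function(d, alternative = "greater") {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  if (length(d) == 0) return(1)
  suppressWarnings(
    stats::wilcox.test(d, alternative = alternative, exact = NULL,
                       correct = TRUE)$p.value)
}

#' Paired rank-biserial correlation
#'
#' `r = (W+ - W-) / (W+ + W-)` where W+ and W- are the sums of the ranks of
#' |d| carried by positive and negative differences.  Zero differences are
#' dropped; r is in \[-1, 1\] and equals +/-1 iff all differences share one
#' sign.
#'
#' @param d numeric vector of paired differences.
#' @return rank-biserial correlation; `NA` when every difference is zero.
#' @export
rank_biserial_paired <- function(d) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  if (length(d) == 0) return(NA_real_)
  r <- rank(abs(d))
  wpos <- sum(r[d > 0])
  wneg <- sum(r[d < 0])
  (wpos - wneg) / (wpos + wneg)
}

#' Two-sample Wilcoxon rank-sum test on delta-beta values
#'
#' Two-sided rank-sum comparison of two sets of methylation differences
#' (e.g. patient vs corrected-clone delta-beta distributions).  Exact for
#' small tie-free samples, otherwise tie-corrected normal approximation.
#'
#' @param delta_a,delta_b numeric vectors (non-empty).
#' @return two-sided p-value; 1 when all values across both samples are
#'   identical.
#' @export
beta_difference_test <- function(delta_a, delta_b) {
  delta_a <- delta_a[!is.na(delta_a)]
  delta_b <- delta_b[!is.na(delta_b)]
  if (length(delta_a) == 0 || length(delta_b) == 0)
    stop("both samples must be non-empty")
  if (length(unique(c(delta_a, delta_b))) == 1) return(1)
  suppressWarnings(
    stats::wilcox.test(delta_a, delta_b, alternative = "two.sided",
                       exact = NULL, correct = TRUE)$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] kept as the package's single
#' FDR entry point.
#'
#' @param p numeric vector of p-values.
#' @return BH-adjusted values, same order as input.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
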