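## Per-CpG two-group differential methylation: pooled-variance t-tests on
## beta values, BH FDR, thresholded call sets, and Venn partitioning.

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `fdr_i = min_{j: p_(j) >= p_(i)} p_(j) * m /
#' rank(j)`, capped at 1, in the original order.  Inputs are validated to
#' lie in `[0, 1]`; the computation is delegated to
#' `stats::p.adjust(method = "BH")`, which implements exactly this step-up
#' rule.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted FDR values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (anyNA(p)) stop("p contains missing values")
  if (any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-group per-CpG differential methylation test
#'
#' For every probe with enough non-missing values in both groups, computes
#' group means, the delta-beta (`test - reference`), a two-sided
#' pooled-variance (Student's) t-test, and BH FDR over all tested probes.
#' Probes with missing values in more than `max_missing` of either group,
#' or fewer than 2 usable samples in a group, are skipped.
#'
#' Zero-pooled-variance probes get `p = 1` when the means are equal and
#' `p = 0` when they differ (degenerate-variance convention).
#'
#' @param beta Beta matrix (probes x samples, rownames/colnames set).
#' @param ref_ids,test_ids Column names of the reference and test groups.
#' @param max_missing Maximum tolerated missing fraction per group per probe.
#' @param var_equal Pooled-variance t (default); `FALSE` gives Welch.
#' @return A `data.frame` (one row per tested probe): `probe_id`, `mean_a`
#'   (reference), `mean_b` (test), `delta_beta`, `t_stat`, `df`, `p_value`,
#'   `fdr`, `n_a`, `n_b`.
#' @export
compare_groups <- function(beta, ref_ids, test_ids, max_missing = 0.2,
                           var_equal = TRUE) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  if (!length(ref_ids) || !length(test_ids)) stop("empty sample group")
  missing <- setdiff(c(ref_ids, test_ids), colnames(beta))
  if (length(missing)) stop("sample(s) not in beta matrix: ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  if (length(ref_ids) < 2L || length(test_ids) < 2L) {
    stop("each group needs at least 2 samples")
  }
  A <- beta[, ref_ids, drop = FALSE]
  B <- beta[, test_ids, drop = FALSE]
  nA <- rowSums(!is.na(A)); nB <- rowSums(!is.na(B))
  keep <- nA >= 2L & nB >= 2L &
    (1 - nA / length(ref_ids)) <= max_missing &
    (1 - nB / length(test_ids)) <= max_missing
  if (!any(keep)) stop("no probe passes the missingness filter")
  A <- A[keep, , drop = FALSE]; B <- B[keep, , drop = FALSE]
  nA <- nA[keep]; nB <- nB[keep]
  mA <- rowMeans(A, na.rm = TRUE); mB <- rowMeans(B, na.rm = TRUE)
  vA <- pmax(rowSums((A - mA)^2, na.rm = TRUE) / (nA - 1L), 0)
  vB <- pmax(rowSums((B - mB)^2, na.rm = TRUE) / (nB - 1L), 0)
  delta <- mB - mA
  if (var_equal) {
    df <- nA + nB - 2L
    sp2 <- ((nA - 1L) * vA + (nB - 1L) * vB) / df
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
  } else {
    se <- sqrt(vA / nA + vB / nB)
    df <- (vA / nA + vB / nB)^2 /
      ((vA / nA)^2 / (nA - 1L) + (vB / nB)^2 / (nB - 1L))
  }
  t_stat <- delta / se
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  degen <- se == 0
  if (any(degen)) {
    p[degen] <- ifelse(delta[degen] == 0, 1, 0)
    t_stat[degen] <- ifelse(delta[degen] == 0, 0,
                            sign(delta[degen]) * Inf)
  }
  data.frame(probe_id = rownames(A), mean_a = mA, mean_b = mB,
             delta_beta = delta, t_stat = t_stat, df = df,
             p_value = p, fdr = bh_adjust(p),
             n_a = nA, n_b = nB, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Threshold a differential table into a call set
#'
#' Hypermethylated calls satisfy `fdr < fdr_max` and
#' `delta_beta > delta_min`; hypomethylated calls `delta_beta < -delta_min`
#' (strict inequalities).  `use_raw_p = TRUE` thresholds the raw p-value
#' instead of the FDR, for analyses defined on unadjusted significance.
#'
#' @param diff Output of [compare_groups()].
#' @param fdr_max,delta_min Positive thresholds.
#' @param comparison Label stored in the call set.
#' @param use_raw_p Threshold `p_value` rather than `fdr`.
#' @return An object of class `cpg_calls`: list with `comparison`, `hyper`,
#'   `hypo` (probe id vectors), and the thresholds used.
#' @export
call_cpgs <- function(diff, fdr_max = 0.05, delta_min = 0.1,
                      comparison = "comparison", use_raw_p = FALSE) {
  stopifnot(fdr_max > 0, delta_min > 0)
  sig <- if (use_raw_p) diff$p_value < fdr_max else diff$fdr < fdr_max
  structure(list(comparison = comparison,
                 hyper = diff$probe_id[sig & diff$delta_beta > delta_min],
                 hypo = diff$probe_id[sig & diff$delta_beta < -delta_min],
                 fdr_max = fdr_max, delta_min = delta_min,
                 use_raw_p = use_raw_p),
            class = "cpg_calls")
}

#' @export
print.cpg_calls <- function(x, ...) {
  cat(sprintf("CpG call set '%s': %d hyper, %d hypo (%s<%g, |delta beta|>%g)\n",
              x$comparison, length(x$hyper), length(x$hypo),
              if (isTRUE(x$use_raw_p)) "p" else "FDR", x$fdr_max, x$delta_min))
  invisible(x)
}

#' All called probes of a call set
#'
#' @param calls A `cpg_calls` object.
#' @param direction `"both"` (hyper union hypo), `"hyper"` or `"hypo"`.
#' @return Character vector of probe ids.
#' @export
call_members <- function(calls, direction = "both") {
  switch(direction,
         both = union(calls$hyper, calls$hypo),
         hyper = calls$hyper,
         hypo = calls$hypo,
         stop("direction must be 'both', 'hyper' or 'hypo'"))
}

#' Venn partition of 2-3 call sets
#'
#' Partitions the union of set memberships (hyper union hypo per set) into
#' exclusive regions: unique to each set, each pairwise-only overlap, and
#' the all-sets core.
#'
#' @param call_sets List of 2-3 `cpg_calls` objects or plain character
#'   vectors of probe ids.
#' @param labels Optional set labels (defaults to comparison labels or
#'   list names).
#' @return A `data.frame` with columns `region` (labels joined by `&`),
#'   `n_sets`, and `count`; rows cover every region, including empty ones.
#' @export
venn_partition <- function(call_sets, labels = NULL) {
  k <- length(call_sets)
  if (k < 2L || k > 3L) {
    stop("venn_partition handles 2 or 3 sets; for more, tabulate a matrix")
  }
  sets <- lapply(call_sets, function(s) {
    if (inherits(s, "cpg_calls")) call_members(s) else unique(as.character(s))
  })
  if (is.null(labels)) {
    labels <- if (!is.null(names(call_sets)) && all(nzchar(names(call_sets)))) {
      names(call_sets)
    } else {
      vapply(seq_along(call_sets), function(i) {
        s <- call_sets[[i]]
        if (inherits(s, "cpg_calls")) s$comparison else paste0("set", i)
      }, "")
    }
  }
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (!length(universe)) member <- matrix(logical(), 0L, k)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  region <- apply(patterns, 1L, function(w) paste(labels[as.logical(w)],
                                                  collapse = "&"))
  count <- apply(patterns, 1L, function(w) {
    sum(apply(member, 1L, function(m) all(m == as.logical(w))))
  })
  data.frame(region = region, n_sets = rowSums(patterns), count = as.integer(count),
             row.names = NULL, stringsAsFactors = FALSE)
}
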