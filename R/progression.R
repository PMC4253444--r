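## Stage-wise call counting, cirrhosis-to-HCC conservation, per-sample
## hypermethylation frequency, and primary-to-culture conservation.

#' Differential-call counts per disease stage
#'
#' For each stage bin — cirrhosis, HCC T1+T2, HCC T3+T4 by default — runs
#' [compare_groups()] against the normal reference and counts thresholded
#' calls.
#'
#' @param beta Beta matrix.
#' @param sheet Sample sheet (`tissue_class`, `tnm_stage`).
#' @param stages Named list; each element is either `"cirrhosis"` or a
#'   vector of TNM stages defining an HCC bin.
#' @param fdr_max,delta_min Call thresholds (defaults follow the high
#'   stringency stage analysis: FDR < 0.05, |delta beta| > 0.25).
#' @param etiology Optional etiology filter applied to the disease groups.
#' @return A `data.frame`: `stage`, `n_samples`, `n_hyper`, `n_hypo`,
#'   `n_total`.
#' @export
stage_call_counts <- function(beta, sheet,
                              stages = list(cirrhosis = "cirrhosis",
                                            "T1+T2" = c("T1", "T2"),
                                            "T3+T4" = c("T3", "T4")),
                              fdr_max = 0.05, delta_min = 0.25,
                              etiology = NULL) {
  normal_ids <- sheet$sample_id[sheet$tissue_class == "normal"]
  if (length(normal_ids) < 2L) stop("need at least 2 normal samples")
  et_ok <- if (is.null(etiology)) rep(TRUE, nrow(sheet))
           else sheet$etiology %in% etiology
  rows <- lapply(names(stages), function(st) {
    def <- stages[[st]]
    ids <- if (identical(def, "cirrhosis")) {
      sheet$sample_id[sheet$tissue_class == "cirrhosis" & et_ok]
    } else {
      sheet$sample_id[sheet$tissue_class == "HCC" & et_ok &
                        sheet$tnm_stage %in% def]
    }
    if (length(ids) < 2L) stop("stage '", st, "' has fewer than 2 samples")
    calls <- call_cpgs(compare_groups(beta, normal_ids, ids),
                       fdr_max = fdr_max, delta_min = delta_min,
                       comparison = st)
    data.frame(stage = st, n_samples = length(ids),
               n_hyper = length(calls$hyper), n_hypo = length(calls$hypo),
               n_total = length(calls$hyper) + length(calls$hypo),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Direction-aware overlap between an early and a late call set
#'
#' Hyper calls are intersected with hyper calls and hypo with hypo.
#'
#' @param set_early,set_late `cpg_calls` objects.
#' @return List: `n_overlap`, `frac_early_conserved` (overlap / early set
#'   size), `frac_late_prefigured` (overlap / late set size); fractions are
#'   0 for empty sets.
#' @export
stage_overlap <- function(set_early, set_late) {
  ov <- length(intersect(set_early$hyper, set_late$hyper)) +
    length(intersect(set_early$hypo, set_late$hypo))
  n_early <- length(set_early$hyper) + length(set_early$hypo)
  n_late <- length(set_late$hyper) + length(set_late$hypo)
  list(n_overlap = ov,
       frac_early_conserved = if (n_early) ov / n_early else 0,
       frac_late_prefigured = if (n_late) ov / n_late else 0)
}

#' Per-sample aberrant-methylation frequency
#'
#' A disease sample is called aberrant at a probe when its beta deviates
#' from the normal-group mean by more than `delta` in the given direction;
#' the frequency is the fraction of non-missing disease samples called.
#'
#' @param beta Beta matrix.
#' @param normal_ids,disease_ids Sample columns of the reference and
#'   disease groups.
#' @param probes Probe ids to evaluate (default: all rows).
#' @param delta Per-sample margin (default 0.25).
#' @param direction `"hyper"` (default) or `"hypo"`.
#' @return A `data.frame`: `probe_id`, `n_called`, `n_samples` (non-missing
#'   disease samples), `frequency` (`NA` when all disease values missing).
#' @export
sample_hyper_frequency <- function(beta, normal_ids, disease_ids,
                                   probes = NULL, delta = 0.25,
                                   direction = c("hyper", "hypo")) {
  direction <- match.arg(direction)
  if (!length(normal_ids) || !length(disease_ids)) stop("empty sample group")
  if (is.null(probes)) probes <- rownames(beta)
  missing <- setdiff(probes, rownames(beta))
  if (length(missing)) stop("probe(s) absent from beta matrix: ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  ref <- rowMeans(beta[probes, normal_ids, drop = FALSE], na.rm = TRUE)
  dis <- beta[probes, disease_ids, drop = FALSE]
  called <- if (direction == "hyper") dis - ref > delta else dis - ref < -delta
  n_called <- rowSums(called, na.rm = TRUE)
  n_samples <- rowSums(!is.na(dis))
  data.frame(probe_id = probes, n_called = n_called, n_samples = n_samples,
             frequency = ifelse(n_samples > 0, n_called / n_samples, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Conservation of primary-tissue calls in a culture comparison
#'
#' Fraction of primary hypermethylated (hypomethylated) calls whose
#' delta-beta in the culture comparison exceeds `+delta_min` (falls below
#' `-delta_min`).  Call probes absent from the culture table are reported
#' and excluded from the denominators.
#'
#' @param primary_calls `cpg_calls` from the primary-tissue comparison.
#' @param culture_diff Differential table of the culture comparison
#'   (e.g. HCC cell lines vs cultured hepatocytes).
#' @param delta_min Conservation margin (default 0.25).
#' @return List: `hyper` and `hypo` conserved fractions (`NA` for an empty
#'   direction), `n_hyper`, `n_hypo` covered calls, `n_uncovered`.
#' @export
culture_conservation <- function(primary_calls, culture_diff,
                                 delta_min = 0.25) {
  d <- stats::setNames(culture_diff$delta_beta, culture_diff$probe_id)
  frac <- function(probes, sgn) {
    covered <- probes[probes %in% names(d)]
    if (!length(covered)) return(list(frac = NA_real_, n = 0L))
    list(frac = mean(sgn * d[covered] > delta_min), n = length(covered))
  }
  hy <- frac(primary_calls$hyper, 1)
  ho <- frac(primary_calls$hypo, -1)
  n_uncov <- sum(!primary_calls$hyper %in% names(d)) +
    sum(!primary_calls$hypo %in% names(d))
  list(hyper = hy$frac, hypo = ho$frac, n_hyper = hy$n, n_hypo = ho$n,
       n_uncovered = n_uncov)
}
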