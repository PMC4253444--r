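## Differentially methylated regions as maximal runs of consecutive,
## consistently shifted probes in manifest (array) order.

#' Find DMRs as maximal consecutive-probe runs
#'
#' Probes are walked in genomic order within each chromosome.  A run
#' accumulates while `|delta_beta| > delta_min` with constant sign (and
#' `fdr < fdr_max` when `require_fdr` is on); any non-qualifying probe
#' (including probes absent from `diff`, e.g. filtered for missingness),
#' a sign change, a chromosome change, or — when `max_gap` is set — a
#' genomic gap larger than `max_gap` bp breaks the run.  Maximal runs of at
#' least `min_run` probes are reported.
#'
#' @param diff Differential table from [compare_groups()].
#' @param manifest Probe manifest (sorted; see [read_manifest()]).
#' @param min_run Minimum probes per DMR (>= 2).
#' @param delta_min Minimum absolute delta-beta (strict).
#' @param require_fdr Also require per-probe `fdr < fdr_max`.
#' @param fdr_max FDR threshold used when `require_fdr` is on.
#' @param max_gap Optional maximum bp distance between consecutive member
#'   probes; `NULL` (default) imposes no distance cap, matching an
#'   array-order definition of "consecutive".
#' @return A `data.frame`, one row per DMR: `chr`, `start`, `end` (1-based
#'   inclusive positions of the first/last member probe), `n_cpgs`,
#'   `direction` (`hyper`/`hypo`), `mean_delta_beta`, `length_bp`, and a
#'   `probes` list-column of member probe ids.
#' @export
find_dmrs <- function(diff, manifest, min_run = 10L, delta_min = 0.1,
                      require_fdr = FALSE, fdr_max = 0.05, max_gap = NULL) {
  if (min_run < 2L) stop("min_run must be at least 2")
  m <- sort_manifest(manifest)
  i <- match(m$probe_id, diff$probe_id)
  delta <- diff$delta_beta[i]
  fdr <- diff$fdr[i]
  qual <- !is.na(delta) & abs(delta) > delta_min
  if (require_fdr) qual <- qual & !is.na(fdr) & fdr < fdr_max
  state <- ifelse(qual, sign(delta), 0)
  n <- nrow(m)
  if (!n) return(empty_dmrs())
  new_run <- c(TRUE, m$chr[-1L] != m$chr[-n] | state[-1L] != state[-n])
  if (!is.null(max_gap)) {
    gap_break <- c(FALSE, (m$pos[-1L] - m$pos[-n]) > max_gap)
    new_run <- new_run | gap_break
  }
  run_id <- cumsum(new_run)
  run_len <- tabulate(run_id)
  ## the state is constant within a run by construction; index by first member
  run_first <- which(new_run)
  keep_run <- state[run_first] != 0 & run_len >= min_run
  ids <- which(keep_run)
  if (!length(ids)) return(empty_dmrs())
  out <- lapply(ids, function(r) {
    idx <- which(run_id == r)
    data.frame(chr = m$chr[idx[1L]],
               start = m$pos[idx[1L]],
               end = m$pos[idx[length(idx)]],
               n_cpgs = length(idx),
               direction = if (state[idx[1L]] > 0) "hyper" else "hypo",
               mean_delta_beta = mean(delta[idx]),
               probes = I(list(m$probe_id[idx])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$length_bp <- out$end - out$start + 1L
  out <- out[order(chrom_rank(out$chr), out$start),
             c("chr", "start", "end", "n_cpgs", "direction",
               "mean_delta_beta", "length_bp", "probes")]
  rownames(out) <- NULL
  out
}

empty_dmrs <- function() {
  data.frame(chr = character(), start = integer(), end = integer(),
             n_cpgs = integer(), direction = character(),
             mean_delta_beta = numeric(), length_bp = integer(),
             probes = I(list()), stringsAsFactors = FALSE)
}

#' Summarize a DMR list per direction
#'
#' @param dmrs DMR table from [find_dmrs()].
#' @return A `data.frame` with one row per direction: `dmr_count`,
#'   `mean_length_bp`, `median_length_bp`, `total_cpgs` (zeros when no DMR
#'   of that direction exists).
#' @export
summarize_dmrs <- function(dmrs) {
  do.call(rbind, lapply(c("hyper", "hypo"), function(d) {
    sel <- dmrs$direction == d
    n <- sum(sel)
    data.frame(direction = d,
               dmr_count = n,
               mean_length_bp = if (n) mean(dmrs$length_bp[sel]) else 0,
               median_length_bp = if (n) stats::median(dmrs$length_bp[sel]) else 0,
               total_cpgs = if (n) sum(dmrs$n_cpgs[sel]) else 0L,
               stringsAsFactors = FALSE)
  }))
}

dmr_member_probes <- function(dmrs, direction) {
  sel <- dmrs$direction == direction
  unique(unlist(dmrs$probes[sel]))
}

#' Fraction of called CpGs lying inside same-direction DMRs
#'
#' @param calls A `cpg_calls` object.
#' @param dmrs DMR table from [find_dmrs()].
#' @return Fraction in `[0, 1]`; 0 (with a warning) for an empty call set.
#' @export
fraction_of_calls_in_dmrs <- function(calls, dmrs) {
  called <- length(calls$hyper) + length(calls$hypo)
  if (!called) {
    warning("empty call set; fraction defined as 0")
    return(0)
  }
  inside <- sum(calls$hyper %in% dmr_member_probes(dmrs, "hyper")) +
    sum(calls$hypo %in% dmr_member_probes(dmrs, "hypo"))
  inside / called
}

#' Probes shared between the DMRs of two comparisons
#'
#' @param dmrs_a,dmrs_b DMR tables from [find_dmrs()].
#' @return List with `hyper` and `hypo` probe-id intersections.
#' @export
shared_dmr_probes <- function(dmrs_a, dmrs_b) {
  list(hyper = intersect(dmr_member_probes(dmrs_a, "hyper"),
                         dmr_member_probes(dmrs_b, "hyper")),
       hypo = intersect(dmr_member_probes(dmrs_a, "hypo"),
                        dmr_member_probes(dmrs_b, "hypo")))
}
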