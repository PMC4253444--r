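## Gene-level expression summaries, quartile strata, and
## expression-stratified metagene profiles.

#' Summarize probe-level expression to genes
#'
#' Per-gene mean of all member-probe intensities across all samples, on the
#' given intensity scale (set `log2 = TRUE` to average `log2(x + 1)`
#' intensities instead).
#'
#' @param intensities Probe x sample numeric matrix with probe rownames.
#' @param probe_gene Map `data.frame` with columns `probe_id`, `gene`.
#' @param log2 Average on the log2 scale.
#' @return A `data.frame`: `gene`, `mean_intensity`, `n_probes`; attributes
#'   `n_samples` and `n_unmapped` (probes ignored for lacking a gene).
#' @export
summarize_expression <- function(intensities, probe_gene, log2 = FALSE) {
  stopifnot(is.matrix(intensities), !is.null(rownames(intensities)),
            all(c("probe_id", "gene") %in% names(probe_gene)))
  gene <- probe_gene$gene[match(rownames(intensities), probe_gene$probe_id)]
  unmapped <- is.na(gene)
  x <- intensities[!unmapped, , drop = FALSE]
  if (!nrow(x)) stop("no probe maps to a gene")
  if (log2) x <- log2(x + 1)
  gene <- gene[!unmapped]
  means <- tapply(rowMeans(x, na.rm = TRUE), gene, mean)
  out <- data.frame(gene = names(means), mean_intensity = as.numeric(means),
                    n_probes = as.integer(table(gene)[names(means)]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_samples") <- ncol(intensities)
  attr(out, "n_unmapped") <- sum(unmapped)
  out
}

#' Top/bottom expression quartile strata
#'
#' Nearest-rank quantiles: the `floor(q * n)` most and least expressed
#' genes, with ties broken by gene id for determinism.
#'
#' @param summary Output of [summarize_expression()].
#' @param q Stratum fraction in `(0, 0.5)`; default 0.25 (quartiles).
#' @return List with `high` and `low` gene-id vectors (disjoint).
#' @export
expression_strata <- function(summary, q = 0.25) {
  if (q <= 0 || q >= 0.5) stop("q must be in (0, 0.5)")
  n <- nrow(summary)
  if (n < 4L) stop("need at least 4 genes")
  if (diff(range(summary$mean_intensity)) == 0) {
    stop("degenerate expression summary: all genes have identical intensity")
  }
  n_take <- floor(q * n)
  ord <- order(summary$mean_intensity, summary$gene)
  list(high = summary$gene[rev(ord)][seq_len(n_take)],
       low = summary$gene[ord][seq_len(n_take)])
}

#' Expression-stratified metagene profiles
#'
#' Builds one metagene profile of mean beta per expression stratum,
#' restricting the gene models to that stratum's genes.
#'
#' @param beta Beta matrix (mean beta per probe is profiled).
#' @param manifest Probe manifest.
#' @param genes Gene models.
#' @param strata Named list of gene-id vectors (e.g. from
#'   [expression_strata()]).
#' @param ... Passed to [metagene_profile()].
#' @return Named list of metagene profile `data.frame`s.
#' @export
stratified_metagene <- function(beta, manifest, genes, strata, ...) {
  stopifnot(is.matrix(beta), is.list(strata), length(strata) >= 1L)
  values <- rowMeans(beta, na.rm = TRUE)
  lapply(strata, function(gs) {
    if (!length(gs)) stop("empty expression stratum")
    missing <- setdiff(gs, genes$gene)
    if (length(missing)) {
      stop("stratum gene(s) absent from gene models: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
    metagene_profile(values, manifest, genes[genes$gene %in% gs, , drop = FALSE],
                     ...)
  })
}
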