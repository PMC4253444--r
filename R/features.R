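## Distribution of calls across island/genic features, per-gene
## feature-level differentials, and metagene (tag-density) profiles.

#' Distribution of calls across annotation categories
#'
#' Counts and proportions of called probes per island relation and per
#' genic feature, separately for hyper- and hypomethylated calls.
#'
#' @param calls A `cpg_calls` object (probes must be in the manifest).
#' @param manifest Probe manifest.
#' @return A long `data.frame`: `direction`, `vocabulary`
#'   (`island`/`genic`), `category`, `count`, `proportion` (proportions are
#'   `NA` when that direction has no calls).
#' @export
feature_distribution <- function(calls, manifest) {
  missing <- setdiff(c(calls$hyper, calls$hypo), manifest$probe_id)
  if (length(missing)) {
    stop("called probe(s) absent from manifest: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  one <- function(probes, direction) {
    m <- manifest[manifest$probe_id %in% probes, , drop = FALSE]
    n <- nrow(m)
    rbind(
      data.frame(direction = direction, vocabulary = "island",
                 category = island_relations(),
                 count = as.integer(table(factor(m$island, island_relations()))),
                 stringsAsFactors = FALSE),
      data.frame(direction = direction, vocabulary = "genic",
                 category = genic_features(),
                 count = as.integer(table(factor(m$feature, genic_features()))),
                 stringsAsFactors = FALSE)
    ) |> transform(proportion = if (n) count / n else NA_real_)
  }
  out <- rbind(one(calls$hyper, "hyper"), one(calls$hypo, "hypo"))
  rownames(out) <- NULL
  out
}

#' Mean delta-beta per gene and genic feature
#'
#' @param diff Differential table from [compare_groups()].
#' @param manifest Probe manifest with gene annotations.
#' @return A `data.frame`: one row per annotated gene, one column per genic
#'   feature (mean member-probe delta-beta; `NA` where the gene has no
#'   probes in that feature).
#' @export
per_gene_feature_delta <- function(diff, manifest) {
  m <- manifest[match(diff$probe_id, manifest$probe_id), , drop = FALSE]
  keep <- !is.na(m$gene) & m$feature != "Intergenic"
  if (!any(keep)) {
    out <- data.frame(gene = character(), stringsAsFactors = FALSE)
    for (f in setdiff(genic_features(), "Intergenic")) out[[f]] <- numeric()
    return(out)
  }
  feats <- setdiff(genic_features(), "Intergenic")
  tab <- tapply(diff$delta_beta[keep],
                list(gene = m$gene[keep], feature = factor(m$feature[keep], feats)),
                mean)
  out <- data.frame(gene = rownames(tab), stringsAsFactors = FALSE)
  for (f in feats) out[[f]] <- as.numeric(tab[, f])
  rownames(out) <- NULL
  out
}

#' Correlation and regression between two per-gene features
#'
#' Pearson correlation and least-squares line over genes with both
#' features non-missing.
#'
#' @param per_gene Table from [per_gene_feature_delta()].
#' @param feat_x,feat_y Feature column names.
#' @return List with `r`, `slope`, `intercept`, `p` (correlation test
#'   p-value) and `n` complete pairs.
#' @export
feature_correlation <- function(per_gene, feat_x, feat_y) {
  stopifnot(feat_x %in% names(per_gene), feat_y %in% names(per_gene))
  x <- per_gene[[feat_x]]; y <- per_gene[[feat_y]]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("need at least 3 genes with both features non-missing")
  x <- x[ok]; y <- y[ok]
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]), p = ct$p.value, n = sum(ok))
}

#' Metagene (tag-density) profile
#'
#' Averages per-probe values over genes in strand-oriented gene
#' coordinates: an upstream flank of `flank` bp (binned by bp offset), the
#' gene body rescaled to percent of gene length, and a downstream flank.
#' Probes contribute to every gene whose extended window covers them.
#'
#' @param values Named numeric vector (probe id -> beta or delta-beta).
#' @param manifest Probe manifest.
#' @param genes Gene models: `gene`, `chr`, `strand`, `tss`, `tts`.
#' @param flank Flank width in bp on each side (default 5000).
#' @param flank_bins,body_bins Bin counts for each flank and the body.
#' @return A `data.frame` with one row per bin: `region` (`upstream`,
#'   `body`, `downstream`), `bin` (1..total), `x` (bin-midpoint coordinate:
#'   bp relative to TSS for flanks, percent of gene length for the body),
#'   `mean_value`, `n_probes`.
#' @export
metagene_profile <- function(values, manifest, genes, flank = 5000L,
                             flank_bins = 25L, body_bins = 50L) {
  stopifnot(is.numeric(values), !is.null(names(values)),
            flank > 0, flank_bins >= 1L, body_bins >= 1L)
  m <- manifest[match(names(values), manifest$probe_id), , drop = FALSE]
  ok <- !is.na(m$probe_id)
  m <- m[ok, , drop = FALSE]; v <- unname(values)[ok]
  w <- flank / flank_bins
  n_bins <- 2L * flank_bins + body_bins
  sums <- numeric(n_bins); counts <- integer(n_bins)

  by_chr <- split(seq_len(nrow(m)), m$chr)
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    if (g$tss == g$tts) {
      warning("zero-length gene ", g$gene, " skipped")
      next
    }
    idx <- by_chr[[g$chr]]
    if (is.null(idx)) next
    pos <- m$pos[idx]
    lo <- min(g$tss, g$tts) - flank; hi <- max(g$tss, g$tts) + flank
    idx <- idx[pos >= lo & pos <= hi]
    if (!length(idx)) next
    pos <- m$pos[idx]
    plus <- g$strand == "+"
    d_up <- if (plus) g$tss - pos else pos - g$tss
    d_down <- if (plus) pos - g$tts else g$tts - pos
    frac <- (pos - g$tss) / (g$tts - g$tss)
    bin <- rep(NA_integer_, length(idx))
    up <- d_up > 0 & d_up <= flank
    bin[up] <- flank_bins - ceiling(d_up[up] / w) + 1L
    body <- is.na(bin) & frac >= 0 & frac <= 1
    bin[body] <- flank_bins + pmin(body_bins, floor(frac[body] * body_bins) + 1L)
    down <- is.na(bin) & d_down > 0 & d_down <= flank
    bin[down] <- flank_bins + body_bins + ceiling(d_down[down] / w)
    hit <- !is.na(bin)
    if (!any(hit)) next
    add <- tapply(v[idx][hit], bin[hit], sum)
    where <- as.integer(names(add))
    sums[where] <- sums[where] + as.numeric(add)
    counts[where] <- counts[where] + as.integer(table(bin[hit]))
  }
  region <- rep(c("upstream", "body", "downstream"),
                c(flank_bins, body_bins, flank_bins))
  x <- c(-(flank_bins:1) * w + w / 2,
         (seq_len(body_bins) - 0.5) / body_bins * 100,
         (seq_len(flank_bins) - 0.5) * w)
  data.frame(region = region, bin = seq_len(n_bins), x = x,
             mean_value = ifelse(counts > 0, sums / counts, NA_real_),
             n_probes = counts, stringsAsFactors = FALSE)
}
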