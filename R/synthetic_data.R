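## Synthetic 450k-style cohort generator: probe manifests with island and
## genic geometry, beta-distributed sample values with planted per-etiology
## effects, planted DMR runs, expression coupling, clone tables, and a
## ground-truth record for recovery testing.  Fully deterministic under a
## given seed.

#' Specify a planted differential-methylation effect
#'
#' An effect touches every sample whose tissue class and etiology match, with
#' stage scaling (cirrhosis attenuated, late-stage HCC amplified) applied on
#' top of the base effect size unless `scale_by_stage = FALSE`.
#'
#' @param name Label recorded in the simulation truth.
#' @param tissues Tissue classes carrying the effect (subset of
#'   `c("cirrhosis", "HCC")`).  When `"HCC"` is included, HCC cell lines
#'   inherit the effect (masked per probe by the design's cell-line
#'   conservation fraction) regardless of the effect's etiology, since lines
#'   derive from tumors of mixed etiology.
#' @param etiologies Etiology labels carrying the effect, or `"all"`.
#' @param n Number of probes planted.
#' @param delta Base absolute effect size at the HCC early stage; a length-2
#'   vector gives a per-probe uniform range.
#' @param frac_hyper Fraction of the planted probes that gain methylation.
#' @param scope `"probes"` plants on independent random probes;
#'   `"gene_promoter"` plants a shared per-gene effect on all TSS-proximal
#'   probes of `n` random genes (promoter features shift together, which is
#'   what couples e.g. TSS200 and 1st-exon differentials).
#' @param scale_by_stage Apply cirrhosis/late-stage scaling factors.
#' @return A list describing the effect, for `sim_design(effects = ...)`.
#' @export
sim_effect <- function(name, tissues = "HCC", etiologies = "all", n = 100L,
                       delta = 0.3, frac_hyper = 0.5, scope = "probes",
                       scale_by_stage = TRUE) {
  stopifnot(length(delta) %in% 1:2, all(delta > 0), all(delta < 1),
            frac_hyper >= 0, frac_hyper <= 1, n >= 0,
            scope %in% c("probes", "gene_promoter"),
            all(tissues %in% c("cirrhosis", "HCC")))
  if (!identical(etiologies, "all")) {
    stopifnot(all(etiologies %in% etiologies()))
  }
  list(name = name, tissues = tissues, etiologies = etiologies, n = as.integer(n),
       delta = delta, frac_hyper = frac_hyper, scope = scope,
       scale_by_stage = scale_by_stage)
}

default_effects <- function() {
  list(
    ## HCV dominates cirrhosis and is partly conserved into HCC
    sim_effect("cirr_HCV", tissues = c("cirrhosis", "HCC"), etiologies = "HCV",
               n = 700L, delta = 0.30, frac_hyper = 0.7),
    ## changes shared across cirrhosis etiologies
    sim_effect("cirr_shared", tissues = "cirrhosis",
               etiologies = c("HCV", "EtOH", "HBV"), n = 200L, delta = 0.30,
               frac_hyper = 0.7),
    sim_effect("cirr_EtOH", tissues = "cirrhosis", etiologies = "EtOH",
               n = 60L, delta = 0.30, frac_hyper = 0.6),
    sim_effect("cirr_HBV", tissues = "cirrhosis", etiologies = "HBV",
               n = 30L, delta = 0.30, frac_hyper = 0.6),
    ## alcohol dominates the HCC methylome
    sim_effect("hcc_EtOH", tissues = "HCC", etiologies = "EtOH",
               n = 800L, delta = 0.35, frac_hyper = 0.5),
    sim_effect("hcc_HCV", tissues = "HCC", etiologies = "HCV",
               n = 120L, delta = 0.35, frac_hyper = 0.5),
    sim_effect("hcc_common", tissues = "HCC",
               etiologies = c("HCV", "HBV", "EtOH", "cryptogenic", "other"),
               n = 350L, delta = 0.35, frac_hyper = 0.5),
    ## recurrently hypermethylated marker CpGs, present from cirrhosis onward
    sim_effect("recurrent_hyper", tissues = c("cirrhosis", "HCC"),
               etiologies = "all", n = 100L, delta = 0.40, frac_hyper = 1,
               scale_by_stage = FALSE)
  )
}

#' Describe a synthetic cohort design
#'
#' Holds every tunable of the generator: probe/gene geometry, group sizes,
#' planted single-CpG effects, planted DMR runs, stage scaling, cell-line
#' conservation, and the beta noise precision.  The default is a
#' desk-scale cohort (20,000 probes, groups of 6-15) whose group structure
#' and planted-effect hierarchy mirror a multi-etiology liver cohort;
#' [design_full_cohort()] gives the full-size group layout
#' (156 primary samples plus 25 cultured).
#'
#' @param n_probes Total probes on the synthetic array (>= 100).
#' @param n_chromosomes Number of synthetic autosomes (`chr1`..).
#' @param n_genes Number of gene models placed across chromosomes.
#' @param island_length CpG island length in bp.
#' @param shore_width,shelf_width Widths (bp) of the shore (island edge to
#'   2 kb by default) and shelf (next 2 kb) annuli.
#' @param gene_length_range Uniform range of gene body lengths in bp.
#' @param group_sizes Named integer vector; names are `normal`,
#'   `hepatocyte_culture`, `HCC_cell_line`, or `tissue_etiology` labels such
#'   as `cirrhosis_HCV`, `HCC_EtOH`.
#' @param effects List of [sim_effect()] specs.
#' @param dmr_spec List with `n` (number of planted runs), `len` (probes per
#'   run), `delta`, `frac_hyper`, `tissues`, `etiologies`.
#' @param stage_scaling Named numeric: multiplier for `cirrhosis`, early-stage
#'   (`early`, T1+T2) and late-stage (`late`, T3+T4) HCC effect sizes.
#' @param t12_frac Fraction of HCC samples assigned TNM stage T1 or T2.
#' @param line_conservation Probability that an HCC-scoped planted probe is
#'   conserved in HCC cell lines.
#' @param precision Beta-distribution precision (a+b) of sample noise.
#' @param baseline_low,baseline_high Baseline mean beta at island/TSS-proximal
#'   probes and elsewhere.
#' @param baseline_jitter SD of per-probe Gaussian jitter on the baseline.
#' @param expression_coupling List with `enabled`, `promoter_margin` (beta
#'   shift separating low- from high-expression gene promoters),
#'   `body_margin`, `n_samples`, `probes_per_gene`.
#' @param missing_rate Fraction of beta entries set missing at random.
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(n_probes = 20000L,
                       n_chromosomes = 4L,
                       n_genes = max(8L, round(n_probes / 40)),
                       island_length = 1000L,
                       shore_width = 2000L,
                       shelf_width = 2000L,
                       gene_length_range = c(4000L, 20000L),
                       group_sizes = c(normal = 15L, cirrhosis_HCV = 15L,
                                       cirrhosis_EtOH = 12L, cirrhosis_HBV = 6L,
                                       HCC_HCV = 12L, HCC_EtOH = 15L,
                                       hepatocyte_culture = 10L,
                                       HCC_cell_line = 10L),
                       effects = default_effects(),
                       dmr_spec = list(n = 20L, len = 12L, delta = 0.3,
                                       frac_hyper = 0.5, tissues = "HCC",
                                       etiologies = "all"),
                       stage_scaling = c(cirrhosis = 0.5, early = 1, late = 1.3),
                       t12_frac = 0.63,
                       line_conservation = 0.85,
                       precision = 50,
                       baseline_low = 0.1,
                       baseline_high = 0.8,
                       baseline_jitter = 0.03,
                       expression_coupling = list(enabled = FALSE,
                                                  promoter_margin = 0.3,
                                                  body_margin = 0.15,
                                                  n_samples = 7L,
                                                  probes_per_gene = 3L),
                       missing_rate = 0) {
  stopifnot(n_probes >= 100L, n_chromosomes >= 1L, n_genes >= 8L,
            island_length > 0, shore_width > 0, shelf_width > 0,
            all(group_sizes >= 0), precision > 0,
            baseline_low > 0, baseline_low < 1,
            baseline_high > 0, baseline_high < 1,
            t12_frac >= 0, t12_frac <= 1,
            line_conservation >= 0, line_conservation <= 1,
            missing_rate >= 0, missing_rate < 1)
  lapply(names(group_sizes), parse_group_label)  # validate labels early
  design <- list(n_probes = as.integer(n_probes),
                 n_chromosomes = as.integer(n_chromosomes),
                 n_genes = as.integer(n_genes),
                 island_length = as.integer(island_length),
                 shore_width = as.integer(shore_width),
                 shelf_width = as.integer(shelf_width),
                 gene_length_range = as.integer(gene_length_range),
                 group_sizes = group_sizes,
                 effects = effects,
                 dmr_spec = dmr_spec,
                 stage_scaling = stage_scaling,
                 t12_frac = t12_frac,
                 line_conservation = line_conservation,
                 precision = precision,
                 baseline_low = baseline_low,
                 baseline_high = baseline_high,
                 baseline_jitter = baseline_jitter,
                 expression_coupling = expression_coupling,
                 missing_rate = missing_rate)
  class(design) <- "sim_design"
  design
}

#' Full-size cohort design
#'
#' Same geometry as [sim_design()] but with the full primary cohort layout:
#' 34 normal, 77 cirrhosis (39 HCV / 21 EtOH / 6 HBV / 3 cryptogenic /
#' 8 other), 45 HCC (12 HCV / 2 HBV / 15 EtOH / 6 cryptogenic / 10 other),
#' plus 15 cultured hepatocyte and 10 HCC cell-line samples.
#'
#' @param ... Passed on to [sim_design()].
#' @return A `sim_design` object.
#' @export
design_full_cohort <- function(...) {
  sim_design(group_sizes = c(normal = 34L,
                             cirrhosis_HCV = 39L, cirrhosis_EtOH = 21L,
                             cirrhosis_HBV = 6L, cirrhosis_cryptogenic = 3L,
                             cirrhosis_other = 8L,
                             HCC_HCV = 12L, HCC_HBV = 2L, HCC_EtOH = 15L,
                             HCC_cryptogenic = 6L, HCC_other = 10L,
                             hepatocyte_culture = 15L, HCC_cell_line = 10L),
             ...)
}

parse_group_label <- function(label) {
  if (label %in% c("normal", "hepatocyte_culture", "HCC_cell_line",
                   "metastasis", "biliary")) {
    return(list(tissue = label, etiology = "none"))
  }
  m <- regmatches(label, regexec("^(cirrhosis|HCC)_(.+)$", label))[[1L]]
  if (length(m) == 3L && m[3L] %in% etiologies()) {
    return(list(tissue = m[2L], etiology = m[3L]))
  }
  stop("cannot parse group label '", label,
       "'; use normal/hepatocyte_culture/HCC_cell_line or tissue_etiology")
}

## ---------------------------------------------------------------------------
## manifest simulation

#' Simulate a probe manifest with gene and island geometry
#'
#' Genes are laid non-overlapping along `n_chromosomes` synthetic autosomes,
#' each with a CpG island centered on its TSS (plus occasional intergenic
#' islands).  Probes are placed densely around promoters/islands and more
#' sparsely through gene bodies and intergenic space, then annotated:
#' island relation by distance to the nearest island edge (shore within
#' `shore_width`, shelf within the next `shelf_width`, `N_`/`S_` by genomic
#' side) and genic feature from the gene models (TSS200 within 200 bp
#' upstream of the TSS, TSS1500 within 200-1500 bp, then
#' 5UTR/1stExon/Body/3UTR inside the gene, else Intergenic).
#'
#' @param design A [sim_design()] object.
#' @param seed Integer seed; the same seed reproduces the manifest exactly.
#' @return A list of class `sim_manifest` with elements `manifest`
#'   (see [read_manifest()]), `genes` (gene models with `gene`, `chr`,
#'   `strand`, `tss`, `tts` and, under expression coupling, `expr_class`),
#'   and `islands`.
#' @export
simulate_manifest <- function(design, seed = 1L) {
  stopifnot(inherits(design, "sim_design"))
  with_seed(seed, simulate_manifest_impl(design))
}

simulate_manifest_impl <- function(design) {
  n_chr <- design$n_chromosomes
  chroms <- paste0("chr", seq_len(n_chr))
  genes_per_chr <- diff(round(seq(0, design$n_genes, length.out = n_chr + 1L)))
  u5_len <- 150L; ex1_len <- 350L; u3_len <- 300L
  half_island <- design$island_length %/% 2L

  genes <- list(); islands <- list()
  gi <- 0L
  for (ci in seq_len(n_chr)) {
    cursor <- 10000L
    for (k in seq_len(genes_per_chr[ci])) {
      gi <- gi + 1L
      glen <- round(stats::runif(1, design$gene_length_range[1L],
                                 design$gene_length_range[2L]))
      if (glen <= u5_len + ex1_len + u3_len) {
        stop("design infeasible: gene length ", glen,
             " too short for the 5UTR/1stExon/3UTR layout")
      }
      strand <- sample(c("+", "-"), 1L)
      gstart <- cursor
      gend <- gstart + glen
      tss <- if (strand == "+") gstart else gend
      tts <- if (strand == "+") gend else gstart
      genes[[gi]] <- data.frame(gene = sprintf("GENE%04d", gi), chr = chroms[ci],
                                strand = strand, tss = tss, tts = tts)
      islands[[length(islands) + 1L]] <-
        data.frame(chr = chroms[ci], start = tss - half_island,
                   end = tss + half_island)
      gap <- round(stats::runif(1, 12000, 20000))
      ## occasional intergenic island midway through the gap
      if (stats::runif(1) < 0.3) {
        mid <- gend + gap %/% 2L
        islands[[length(islands) + 1L]] <-
          data.frame(chr = chroms[ci], start = mid - half_island,
                     end = mid + half_island)
      }
      cursor <- gend + gap
    }
  }
  genes <- do.call(rbind, genes)
  islands <- do.call(rbind, islands)
  chrom_len <- vapply(chroms, function(cc) {
    max(c(genes$tss[genes$chr == cc], genes$tts[genes$chr == cc],
          islands$end[islands$chr == cc])) + 10000L
  }, numeric(1))
  if (any(pmax(genes$tss, genes$tts) > chrom_len[genes$chr])) {
    stop("design infeasible: gene extends beyond chromosome end")
  }

  ## probe placement: promoter/island clusters, gene bodies, shelves, gaps
  base_counts <- c(promoter = 9, body = 8, tts = 2, band = 3, gap = 6)
  expected <- design$n_genes * sum(base_counts[c("promoter", "body", "tts", "band")]) +
    design$n_genes * base_counts[["gap"]]
  f <- design$n_probes / expected
  ncount <- function(base, n) {
    x <- base * f
    floor(x) + (stats::runif(n) < x - floor(x))
  }
  pos_list <- list(); chr_list <- list()
  add <- function(chr, pos) {
    pos_list[[length(pos_list) + 1L]] <<- pos
    chr_list[[length(chr_list) + 1L]] <<- rep(chr, length(pos))
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    s <- if (g$strand == "+") 1L else -1L
    np <- ncount(base_counts[["promoter"]], 1L)
    if (np > 0) add(g$chr, g$tss - s * round(stats::runif(np, -600, 1800)))
    nb <- ncount(base_counts[["body"]], 1L)
    if (nb > 0) {
      lo <- min(g$tss, g$tts); hi <- max(g$tss, g$tts)
      add(g$chr, round(stats::runif(nb, lo + 700, hi - 100)))
    }
    nt <- ncount(base_counts[["tts"]], 1L)
    if (nt > 0) add(g$chr, g$tts + round(stats::runif(nt, -500, 500)))
    nband <- ncount(base_counts[["band"]], 1L)
    if (nband > 0) {
      edge_off <- round(stats::runif(nband, 0, design$shore_width + design$shelf_width))
      side <- sample(c(-1L, 1L), nband, replace = TRUE)
      edge <- ifelse(side > 0, g$tss + half_island, g$tss - half_island)
      add(g$chr, edge + side * edge_off)
    }
  }
  ## intergenic probes spread over each chromosome
  for (ci in seq_len(n_chr)) {
    ngap <- ncount(base_counts[["gap"]], 1L) * genes_per_chr[ci]
    if (ngap > 0) add(chroms[ci], round(stats::runif(ngap, 1, chrom_len[ci])))
  }
  probes <- data.frame(chr = unlist(chr_list), pos = as.integer(unlist(pos_list)))
  probes$pos <- pmax(1L, pmin(probes$pos, as.integer(chrom_len[probes$chr])))
  probes <- unique(probes)
  ## trim or pad to exactly n_probes
  if (nrow(probes) > design$n_probes) {
    probes <- probes[sample.int(nrow(probes), design$n_probes), ]
  }
  while (nrow(probes) < design$n_probes) {
    need <- design$n_probes - nrow(probes)
    cc <- sample(chroms, need, replace = TRUE)
    extra <- data.frame(chr = cc,
                        pos = as.integer(round(stats::runif(need, 1, chrom_len[cc]))))
    probes <- unique(rbind(probes, extra))
  }
  probes <- probes[order(chrom_rank(probes$chr), probes$pos), ]
  probes$probe_id <- sprintf("cg%08d", seq_len(nrow(probes)))

  probes$island <- annotate_islands(probes, islands, design$shore_width,
                                    design$shelf_width)
  ann <- annotate_genes(probes, genes, u5_len, ex1_len, u3_len)
  probes$feature <- ann$feature
  probes$gene <- ann$gene

  manifest <- data.frame(probe_id = probes$probe_id, chr = probes$chr,
                         pos = probes$pos,
                         strand = sample(c("+", "-"), nrow(probes), replace = TRUE),
                         gene = probes$gene, feature = probes$feature,
                         island = probes$island,
                         stringsAsFactors = FALSE)
  manifest <- validate_manifest(manifest)

  if (isTRUE(design$expression_coupling$enabled)) {
    n <- nrow(genes)
    q <- floor(n / 4)
    cls <- rep("mid", n)
    idx <- sample.int(n)
    cls[idx[seq_len(q)]] <- "high"
    cls[idx[seq.int(q + 1L, 2L * q)]] <- "low"
    genes$expr_class <- cls
  }
  rownames(genes) <- NULL; rownames(islands) <- NULL
  structure(list(manifest = manifest, genes = genes, islands = islands),
            class = "sim_manifest")
}

annotate_islands <- function(probes, islands, shore_width, shelf_width) {
  out <- rep("OpenSea", nrow(probes))
  for (cc in unique(probes$chr)) {
    pi <- which(probes$chr == cc)
    isl <- islands[islands$chr == cc, , drop = FALSE]
    if (!nrow(isl)) next
    isl <- isl[order(isl$start), , drop = FALSE]
    pos <- probes$pos[pi]
    k <- findInterval(pos, isl$start)  # index of island starting at/before pos
    inside <- k >= 1L & pos <= ifelse(k >= 1L, isl$end[pmax(k, 1L)], -Inf)
    ## distance to previous island's end (probe sits S of it, higher coords)
    d_prev <- ifelse(k >= 1L, pos - isl$end[pmax(k, 1L)], Inf)
    d_prev[d_prev < 0] <- Inf
    ## distance to next island's start (probe sits N of it, lower coords)
    d_next <- ifelse(k < nrow(isl), isl$start[pmin(k + 1L, nrow(isl))] - pos, Inf)
    lab <- rep("OpenSea", length(pos))
    use_next <- d_next <= d_prev  # tie goes to the N side
    d <- ifelse(use_next, d_next, d_prev)
    side <- ifelse(use_next, "N", "S")
    shore <- d <= shore_width
    shelf <- !shore & d <= shore_width + shelf_width
    lab[shore] <- paste0(side[shore], "_Shore")
    lab[shelf] <- paste0(side[shelf], "_Shelf")
    lab[inside] <- "Island"
    out[pi] <- lab
  }
  out
}

annotate_genes <- function(probes, genes, u5_len, ex1_len, u3_len) {
  feature <- rep("Intergenic", nrow(probes))
  gene_of <- rep(NA_character_, nrow(probes))
  for (cc in unique(probes$chr)) {
    pi <- which(probes$chr == cc)
    gg <- genes[genes$chr == cc, , drop = FALSE]
    if (!nrow(gg)) next
    lo <- pmin(gg$tss, gg$tts); hi <- pmax(gg$tss, gg$tts)
    win_lo <- lo - 1500L; win_hi <- hi + 1500L
    ord <- order(win_lo)
    gg <- gg[ord, ]; lo <- lo[ord]; hi <- hi[ord]
    win_lo <- win_lo[ord]; win_hi <- win_hi[ord]
    pos <- probes$pos[pi]
    k <- findInterval(pos, win_lo)
    hit <- k >= 1L & pos <= ifelse(k >= 1L, win_hi[pmax(k, 1L)], -Inf)
    idx <- which(hit)
    if (!length(idx)) next
    g <- pmax(k[idx], 1L)
    p <- pos[idx]
    strand <- gg$strand[g]; tss <- gg$tss[g]; tts <- gg$tts[g]
    d_up <- ifelse(strand == "+", tss - p, p - tss)
    glen <- abs(tts - tss)
    o <- ifelse(strand == "+", p - tss, tss - p)  # oriented offset into gene
    lab <- rep("Intergenic", length(idx))
    in_gene <- o >= 0 & o <= glen
    lab[in_gene & o < u5_len] <- "5UTR"
    lab[in_gene & o >= u5_len & o < u5_len + ex1_len] <- "1stExon"
    lab[in_gene & o >= u5_len + ex1_len & o <= glen - u3_len] <- "Body"
    lab[in_gene & o > glen - u3_len] <- "3UTR"
    lab[d_up > 0 & d_up <= 200] <- "TSS200"
    lab[d_up > 200 & d_up <= 1500] <- "TSS1500"
    feature[pi[idx]] <- lab
    gene_of[pi[idx]] <- ifelse(lab == "Intergenic", NA_character_, gg$gene[g])
  }
  list(feature = feature, gene = gene_of)
}

## ---------------------------------------------------------------------------
## cohort simulation

#' Simulate a sample sheet alone
#'
#' Builds the cohort sample sheet of a design (group labels, TNM stages and
#' clinical covariates) without simulating methylation values.
#'
#' @param design A [sim_design()] object.
#' @param seed Integer seed (covariates are randomized).
#' @return A sample-sheet `data.frame` (see [read_sample_sheet()]) with an
#'   extra `group` column.
#' @export
simulate_sample_sheet <- function(design, seed = 1L) {
  stopifnot(inherits(design, "sim_design"))
  with_seed(seed, build_sample_sheet(design))
}

build_sample_sheet <- function(design) {
  rows <- list()
  sid <- 0L
  for (lab in names(design$group_sizes)) {
    n <- design$group_sizes[[lab]]
    if (n == 0L) next
    pg <- parse_group_label(lab)
    for (i in seq_len(n)) {
      sid <- sid + 1L
      rows[[sid]] <- data.frame(sample_id = sprintf("S%04d", sid),
                                tissue_class = pg$tissue, etiology = pg$etiology,
                                group = lab, stringsAsFactors = FALSE)
    }
  }
  sheet <- do.call(rbind, rows)
  ## TNM stages for HCC samples: first t12_frac alternate T1/T2, rest T3/T4
  sheet$tnm_stage <- NA_character_
  hcc <- which(sheet$tissue_class == "HCC")
  if (length(hcc)) {
    for (lab in unique(sheet$group[hcc])) {
      gidx <- hcc[sheet$group[hcc] == lab]
      n12 <- round(design$t12_frac * length(gidx))
      stages <- c(rep(c("T1", "T2"), length.out = n12),
                  rep(c("T3", "T4"), length.out = length(gidx) - n12))
      sheet$tnm_stage[gidx] <- stages
    }
  }
  sheet$gender <- sample(c("Male", "Female"), nrow(sheet), replace = TRUE,
                         prob = c(0.78, 0.22))
  sheet$differentiation <- NA_integer_
  sheet$differentiation[hcc] <- sample(1:3, length(hcc), replace = TRUE,
                                       prob = c(0.37, 0.52, 0.11))
  sheet$multifocality <- ifelse(sheet$tissue_class == "HCC",
                                sample(c("yes", "no"), nrow(sheet), replace = TRUE),
                                NA_character_)
  sheet$vascularization <- ifelse(sheet$tissue_class == "HCC",
                                  sample(c("yes", "no"), nrow(sheet), replace = TRUE),
                                  NA_character_)
  sheet$tumor_size_class <- ifelse(sheet$tissue_class == "HCC",
                                   sample(c("<5 cm", ">5 cm"), nrow(sheet),
                                          replace = TRUE, prob = c(0.6, 0.4)),
                                   NA_character_)
  sheet$cirrhosis_flag <- ifelse(sheet$tissue_class %in% c("cirrhosis", "HCC"),
                                 ifelse(sheet$tissue_class == "HCC",
                                        sample(c("yes", "no"), nrow(sheet),
                                               replace = TRUE, prob = c(0.96, 0.04)),
                                        "yes"),
                                 NA_character_)
  validate_sample_sheet(sheet)
}

## per-sample multiplier of a planted effect
effect_multiplier <- function(spec, sheet, scaling, conserved = NULL) {
  match_et <- if (identical(spec$etiologies, "all")) rep(TRUE, nrow(sheet))
              else sheet$etiology %in% spec$etiologies
  mult <- numeric(nrow(sheet))
  if ("cirrhosis" %in% spec$tissues) {
    sel <- sheet$tissue_class == "cirrhosis" & match_et
    mult[sel] <- if (spec$scale_by_stage) scaling[["cirrhosis"]] else 1
  }
  if ("HCC" %in% spec$tissues) {
    sel <- sheet$tissue_class == "HCC" & match_et
    late <- sheet$tnm_stage %in% c("T3", "T4")
    if (spec$scale_by_stage) {
      mult[sel & !late] <- scaling[["early"]]
      mult[sel & late] <- scaling[["late"]]
    } else {
      mult[sel] <- 1
    }
    ## cell lines inherit HCC effects regardless of etiology (masked by
    ## per-probe conservation later)
    mult[sheet$tissue_class == "HCC_cell_line"] <- 1
  }
  mult
}

#' Simulate a beta-value cohort with planted effects
#'
#' Baseline probe means are bimodal: `baseline_low` at island or TSS-proximal
#' probes, `baseline_high` elsewhere (with per-probe jitter), optionally
#' shifted per gene-expression class under promoter/body coupling.  Planted
#' effects and DMR runs move the group means; each sample value is then
#' drawn from a beta distribution with that mean and the design precision.
#'
#' @param sim A `sim_manifest` from [simulate_manifest()] (or a bare manifest
#'   `data.frame`, in which case expression coupling is unavailable).
#' @param design The [sim_design()] used (also) to build the manifest.
#' @param seed Integer seed.
#' @return A list of class `sim_cohort`: `beta` (probes x samples matrix),
#'   `sheet` (sample sheet including a `group` column), and `truth`
#'   (planted record: `effects` per-probe table with signed `delta` and
#'   cell-line conservation flags, `dmrs` table with member probes,
#'   `baseline`).
#' @export
simulate_cohort <- function(sim, design, seed = 1L) {
  stopifnot(inherits(design, "sim_design"))
  if (inherits(sim, "sim_manifest")) {
    manifest <- sim$manifest; genes <- sim$genes
  } else {
    manifest <- sim; genes <- NULL
  }
  with_seed(seed, simulate_cohort_impl(manifest, genes, design))
}

simulate_cohort_impl <- function(manifest, genes, design) {
  n_probes <- nrow(manifest)
  sheet <- build_sample_sheet(design)
  n_samples <- nrow(sheet)

  tss_proximal <- manifest$feature %in% c("TSS1500", "TSS200", "5UTR", "1stExon")
  low <- manifest$island == "Island" | tss_proximal
  baseline <- ifelse(low, design$baseline_low, design$baseline_high) +
    stats::rnorm(n_probes, 0, design$baseline_jitter)

  ## expression coupling: low-expression genes get higher promoter beta and
  ## lower body beta than high-expression genes
  cpl <- design$expression_coupling
  if (isTRUE(cpl$enabled)) {
    if (is.null(genes) || is.null(genes$expr_class)) {
      stop("expression coupling requires gene models with expr_class; ",
           "pass the full simulate_manifest() result")
    }
    shift <- c(high = 0, mid = 0.5, low = 1)[genes$expr_class]
    names(shift) <- genes$gene
    gidx <- !is.na(manifest$gene)
    s <- shift[manifest$gene[gidx]]
    promo <- tss_proximal[gidx]
    body <- manifest$feature[gidx] %in% c("Body", "3UTR")
    baseline[gidx][promo] <- baseline[gidx][promo] + cpl$promoter_margin * s[promo]
    baseline[gidx][body] <- baseline[gidx][body] - cpl$body_margin * s[body]
  }
  baseline <- pmin(pmax(baseline, 0.03), 0.97)

  ## ---- plant effects --------------------------------------------------
  used <- logical(n_probes)
  effect_rows <- list()
  means <- matrix(baseline, nrow = n_probes, ncol = n_samples)

  pick_probes <- function(n, hyper) {
    pool <- which(!used & if (hyper) baseline < 0.5 else baseline > 0.5)
    if (length(pool) < n) {
      stop("design infeasible: not enough ", if (hyper) "low" else "high",
           "-baseline probes to plant effect (need ", n, ", have ",
           length(pool), ")")
    }
    sample(pool, n)
  }
  draw_delta <- function(spec, n) {
    if (length(spec$delta) == 2L) stats::runif(n, spec$delta[1L], spec$delta[2L])
    else rep(spec$delta, n)
  }

  apply_effect <- function(spec, idx, delta_signed) {
    mult <- effect_multiplier(spec, sheet, design$stage_scaling)
    conserved <- if ("HCC" %in% spec$tissues) {
      stats::runif(length(idx)) < design$line_conservation
    } else rep(NA, length(idx))
    line_col <- sheet$tissue_class == "HCC_cell_line"
    dmat <- outer(delta_signed, mult)
    if (any(line_col) && "HCC" %in% spec$tissues) {
      dmat[, line_col] <- dmat[, line_col] * ifelse(conserved, 1, 0)
    }
    means[idx, ] <<- means[idx, , drop = FALSE] + dmat
    used[idx] <<- TRUE
    effect_rows[[length(effect_rows) + 1L]] <<-
      data.frame(probe_id = manifest$probe_id[idx], effect = spec$name,
                 delta = delta_signed, conserved_line = conserved,
                 stringsAsFactors = FALSE)
  }

  for (spec in design$effects) {
    if (spec$n == 0L) next
    if (identical(spec$scope, "gene_promoter")) {
      if (is.null(genes)) stop("gene_promoter effects require gene models")
      gsel <- sample(genes$gene, min(spec$n, nrow(genes)))
      ## shared per-gene magnitude so promoter features move together
      gmag <- draw_delta(spec, length(gsel))
      names(gmag) <- gsel
      idx <- which(!used & tss_proximal & manifest$gene %in% gsel)
      if (!length(idx)) next
      sgn <- if (stats::runif(1) < spec$frac_hyper) 1 else -1
      spec_signed <- gmag[manifest$gene[idx]] *
        ifelse(rep(sgn, length(idx)) > 0, 1, -1)
      apply_effect(spec, idx, unname(spec_signed))
    } else {
      n_hyper <- round(spec$n * spec$frac_hyper)
      n_hypo <- spec$n - n_hyper
      if (n_hyper > 0) apply_effect(spec, pick_probes(n_hyper, TRUE),
                                    draw_delta(spec, n_hyper))
      if (n_hypo > 0) apply_effect(spec, pick_probes(n_hypo, FALSE),
                                   -draw_delta(spec, n_hypo))
    }
  }

  ## ---- plant DMR runs -------------------------------------------------
  dmr_rows <- list()
  ds <- design$dmr_spec
  if (!is.null(ds) && ds$n > 0L) {
    dmr_spec <- sim_effect("planted_dmr", tissues = ds$tissues,
                           etiologies = ds$etiologies, n = 0L,
                           delta = ds$delta, frac_hyper = ds$frac_hyper)
    ord_chr <- manifest$chr
    for (d in seq_len(ds$n)) {
      placed <- FALSE
      for (try in 1:200) {
        start <- sample.int(n_probes - ds$len + 1L, 1L)
        idx <- start:(start + ds$len - 1L)
        if (any(used[idx])) next
        if (length(unique(ord_chr[idx])) != 1L) next
        hyper <- stats::runif(1) < ds$frac_hyper
        ## override member baselines into a range compatible with the shift
        baseline[idx] <- if (hyper) stats::runif(ds$len, 0.10, 0.30)
                         else stats::runif(ds$len, 0.60, 0.85)
        means[idx, ] <- baseline[idx]  # reset before re-applying the shift
        delta_signed <- rep(if (hyper) ds$delta else -ds$delta, ds$len)
        apply_effect(dmr_spec, idx, delta_signed)
        dmr_rows[[length(dmr_rows) + 1L]] <-
          data.frame(chr = ord_chr[start], start = manifest$pos[idx[1L]],
                     end = manifest$pos[idx[ds$len]], n_cpgs = ds$len,
                     direction = if (hyper) "hyper" else "hypo",
                     delta = ds$delta,
                     probes = I(list(manifest$probe_id[idx])),
                     stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) stop("design infeasible: could not place planted DMR ", d)
    }
  }

  if (any(means < 0.02 - 1e-9 | means > 0.98 + 1e-9)) {
    stop("planted effects push a group mean outside [0.02, 0.98]")
  }
  means <- pmin(pmax(means, 0.02), 0.98)

  beta <- matrix(stats::rbeta(n_probes * n_samples,
                              shape1 = means * design$precision,
                              shape2 = (1 - means) * design$precision),
                 nrow = n_probes, ncol = n_samples,
                 dimnames = list(manifest$probe_id, sheet$sample_id))
  if (design$missing_rate > 0) {
    beta[stats::runif(length(beta)) < design$missing_rate] <- NA_real_
  }

  truth <- structure(
    list(effects = if (length(effect_rows)) do.call(rbind, effect_rows)
                   else data.frame(probe_id = character(), effect = character(),
                                   delta = numeric(), conserved_line = logical()),
         dmrs = if (length(dmr_rows)) do.call(rbind, dmr_rows)
                else data.frame(chr = character(), start = integer(),
                                end = integer(), n_cpgs = integer(),
                                direction = character(), delta = numeric()),
         baseline = stats::setNames(baseline, manifest$probe_id)),
    class = "sim_truth")
  structure(list(beta = beta, sheet = sheet, truth = truth),
            class = "sim_cohort")
}

## ---------------------------------------------------------------------------
## expression + clone tables

#' Simulate probe-level expression intensities for gene models
#'
#' Multiple intensity probes per gene across a small panel of normal-liver
#' samples.  Under coupling, genes carry their `expr_class` (assigned by
#' [simulate_manifest()] when the design enables coupling): high-expression
#' genes get high intensities and — through the coupled baselines of
#' [simulate_cohort()] — low promoter methylation, and vice versa.
#'
#' @param genes Gene models (`gene` column; `expr_class` used when present
#'   and `coupled = TRUE`).
#' @param n_samples Number of expression columns.
#' @param probes_per_gene Intensity probes per gene.
#' @param coupled Tie intensities to `expr_class`; otherwise intensities are
#'   independent of any methylation structure.
#' @param seed Integer seed.
#' @return A list: `intensities` (probe x sample matrix), `probe_gene`
#'   (probe to gene map), `strata` (truth high/low gene sets, or `NULL`).
#' @export
simulate_expression <- function(genes, n_samples = 7L, probes_per_gene = 3L,
                                coupled = TRUE, seed = 1L) {
  stopifnot(nrow(genes) >= 8L, n_samples >= 1L, probes_per_gene >= 1L)
  with_seed(seed, {
    n <- nrow(genes)
    cls <- if (coupled && !is.null(genes$expr_class)) genes$expr_class
           else rep("mid", n)
    base <- c(high = 12, mid = 8, low = 4)[cls] + stats::rnorm(n, 0, 1)
    if (all(cls == "mid")) base <- 8 + stats::rnorm(n, 0, 2)
    probe_gene <- data.frame(
      probe_id = sprintf("%s_at%d", rep(genes$gene, each = probes_per_gene),
                         seq_len(probes_per_gene)),
      gene = rep(genes$gene, each = probes_per_gene),
      stringsAsFactors = FALSE)
    probe_base <- rep(base, each = probes_per_gene) +
      stats::rnorm(nrow(probe_gene), 0, 0.3)
    intensities <- matrix(probe_base, nrow = nrow(probe_gene), ncol = n_samples) +
      matrix(stats::rnorm(nrow(probe_gene) * n_samples, 0, 0.5),
             nrow = nrow(probe_gene))
    dimnames(intensities) <- list(probe_gene$probe_id,
                                  sprintf("NL%02d", seq_len(n_samples)))
    strata <- if (coupled && !is.null(genes$expr_class)) {
      list(high = genes$gene[genes$expr_class == "high"],
           low = genes$gene[genes$expr_class == "low"])
    }
    list(intensities = intensities, probe_gene = probe_gene, strata = strata)
  })
}

#' Simulate a bisulfite clone table
#'
#' Binary methylation calls for `n_clones` sequenced clones over `n_cpgs`
#' CpG positions, each methylated independently with probability `prob`
#' (scalar or per-CpG vector).
#'
#' @param n_clones Number of clones (rows), >= 1.
#' @param n_cpgs Number of CpG positions (columns).
#' @param prob Methylation probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return An integer 0/1 matrix, clones x CpGs.
#' @export
simulate_clone_table <- function(n_clones, n_cpgs, prob, seed = 1L) {
  stopifnot(n_clones >= 1L, n_cpgs >= 1L)
  if (any(prob < 0 | prob > 1)) stop("prob must be in [0, 1]")
  if (!length(prob) %in% c(1L, n_cpgs)) stop("prob must be scalar or length n_cpgs")
  with_seed(seed, {
    p <- rep(prob, length.out = n_cpgs)
    m <- matrix(stats::rbinom(n_clones * n_cpgs, 1L, rep(p, each = n_clones)),
                nrow = n_clones, ncol = n_cpgs,
                dimnames = list(sprintf("clone%02d", seq_len(n_clones)),
                                sprintf("CpG%02d", seq_len(n_cpgs))))
    m
  })
}
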