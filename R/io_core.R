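## Shared domain vocabularies, file readers/writers and coordinate
## conventions.  Manifest positions are 1-based; all exported
## bedGraph/BED intervals are 0-based half-open (UCSC convention).

#' Controlled vocabularies
#'
#' Category labels used throughout the package: genic features relative to a
#' gene model, CpG-island relations, tissue classes and disease etiologies.
#'
#' @return A character vector of allowed labels.
#' @export
genic_features <- function() {
  c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR", "Intergenic")
}

#' @rdname genic_features
#' @export
island_relations <- function() {
  c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")
}

#' @rdname genic_features
#' @export
tissue_classes <- function() {
  c("normal", "cirrhosis", "HCC", "hepatocyte_culture", "HCC_cell_line",
    "metastasis", "biliary")
}

#' @rdname genic_features
#' @export
etiologies <- function() {
  c("HCV", "HBV", "EtOH", "cryptogenic", "other", "none")
}

tnm_stages <- function() c("T1", "T2", "T3", "T4")

## chromosome rank for canonical sorting: chr1..chrN numerically,
## anything else after, alphabetically
chrom_rank <- function(chr) {
  num <- suppressWarnings(as.integer(sub("^chr", "", chr)))
  key <- ifelse(is.na(num), Inf, num)
  u <- !duplicated(chr)
  lev <- chr[u][order(key[u], chr[u])]
  match(chr, lev)
}

sort_manifest <- function(manifest) {
  manifest[order(chrom_rank(manifest$chr), manifest$pos), , drop = FALSE]
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_delim_file <- function(path) {
  utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""), quote = "\"",
                    comment.char = "")
}

#' Read a beta-value matrix
#'
#' Parses a delimited text file (tab or comma, sniffed from the header) whose
#' first column holds probe ids and remaining columns one sample each.
#' Values must be methylation fractions in `[0, 1]`; empty fields and `NA`
#' are treated as missing.
#'
#' @param path Path to a TSV/CSV file.
#' @return A numeric matrix (probes x samples) with probe ids as rownames.
#' @export
read_beta_matrix <- function(path) {
  df <- read_delim_file(path)
  if (ncol(df) < 2L) stop("beta matrix needs a probe_id column plus >=1 sample column")
  probes <- as.character(df[[1L]])
  dup <- probes[duplicated(probes)]
  if (length(dup)) {
    stop("duplicate probe_id in beta matrix: ", paste(unique(dup), collapse = ", "))
  }
  raw <- as.matrix(df[, -1L, drop = FALSE])
  if (is.character(raw)) {
    num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw),
                                  dimnames = dimnames(raw)))
    bad <- which(!is.na(raw) & is.na(num), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("non-numeric beta value '%s' at probe %s, sample %s",
                   raw[bad[1L, , drop = FALSE]], probes[bad[1L, 1L]],
                   colnames(raw)[bad[1L, 2L]]))
    }
    raw <- num
  }
  storage.mode(raw) <- "double"
  out <- which(raw < 0 | raw > 1, arr.ind = TRUE)
  if (nrow(out)) {
    stop(sprintf("beta value out of [0,1] (%g) at probe %s, sample %s",
                 raw[out[1L, , drop = FALSE]], probes[out[1L, 1L]],
                 colnames(raw)[out[1L, 2L]]))
  }
  rownames(raw) <- probes
  raw
}

#' Write a beta-value matrix
#'
#' @param beta Numeric matrix with probe rownames and sample colnames.
#' @param path Output path; tab-separated with a `probe_id` first column.
#' @param digits Number of decimal digits written (default 6).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path, digits = 6L) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)))
  df <- data.frame(probe_id = rownames(beta),
                   round(beta, digits),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe manifest
#'
#' Expects columns `probe_id, chr, pos, strand, gene, feature, island`
#' (tab or comma separated).  The result is canonically sorted by
#' (chromosome, position); positions are 1-based and must be unique within
#' a chromosome.  Feature and island labels are validated against
#' [genic_features()] and [island_relations()].
#'
#' @param path Path to the manifest file.
#' @param autosomes If `TRUE` (default) the manifest is restricted to
#'   chr1..chr22 before validation, mirroring autosome-only array analyses.
#' @return A `data.frame` with the columns above.
#' @export
read_manifest <- function(path, autosomes = TRUE) {
  df <- read_delim_file(path)
  need <- c("probe_id", "chr", "pos", "strand", "gene", "feature", "island")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  df <- df[, need]
  df$probe_id <- as.character(df$probe_id)
  df$chr <- as.character(df$chr)
  df$pos <- as.integer(df$pos)
  df$gene <- as.character(df$gene)
  validate_manifest(df, autosomes = autosomes)
}

validate_manifest <- function(df, autosomes = FALSE) {
  if (autosomes) {
    df <- df[df$chr %in% paste0("chr", 1:22), , drop = FALSE]
    if (!nrow(df)) stop("no autosomal (chr1..chr22) probes in manifest")
  }
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup)) stop("duplicate probe_id in manifest: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(df$feature), genic_features())
  if (length(bad)) {
    stop("unknown genic feature token(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(genic_features(), collapse = ", "))
  }
  bad <- setdiff(unique(df$island), island_relations())
  if (length(bad)) {
    stop("unknown island relation token(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(island_relations(), collapse = ", "))
  }
  bad <- setdiff(unique(df$strand), c("+", "-"))
  if (length(bad)) stop("strand must be '+' or '-', got: ", paste(bad, collapse = ", "))
  if (any(is.na(df$pos)) || any(df$pos < 1L)) stop("manifest positions must be 1-based positive integers")
  df <- sort_manifest(df)
  same <- df$chr[-1L] == df$chr[-nrow(df)] & df$pos[-1L] == df$pos[-nrow(df)]
  if (nrow(df) > 1L && any(same)) {
    i <- which(same)[1L]
    stop(sprintf("duplicate position %s:%d in manifest (probes %s, %s)",
                 df$chr[i], df$pos[i], df$probe_id[i], df$probe_id[i + 1L]))
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_manifest
#' @param manifest Manifest `data.frame` to write.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Requires columns `sample_id`, `tissue_class` and `etiology`; any further
#' clinical covariate columns (e.g. `tnm_stage`, `gender`, `differentiation`)
#' are carried through unchanged.  `tnm_stage` may only be set for HCC
#' samples.
#'
#' @param path Path to the sample sheet (tab or comma separated).
#' @return A `data.frame`, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- read_delim_file(path)
  need <- c("sample_id", "tissue_class", "etiology")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet is missing columns: ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(df$tissue_class), tissue_classes())
  if (length(bad)) {
    stop("unknown tissue_class token(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(tissue_classes(), collapse = ", "))
  }
  bad <- setdiff(unique(df$etiology), etiologies())
  if (length(bad)) {
    stop("unknown etiology token(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(etiologies(), collapse = ", "))
  }
  if ("tnm_stage" %in% names(df)) {
    staged <- !is.na(df$tnm_stage) & df$tnm_stage != ""
    bad <- setdiff(unique(df$tnm_stage[staged]), tnm_stages())
    if (length(bad)) stop("unknown tnm_stage token(s): ", paste(bad, collapse = ", "))
    off <- staged & df$tissue_class != "HCC"
    if (any(off)) {
      stop("tnm_stage set for non-HCC sample(s): ",
           paste(df$sample_id[off], collapse = ", "))
    }
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_sample_sheet
#' @param sheet Sample sheet `data.frame` to write.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export per-probe values as a bedGraph track
#'
#' Each probe becomes a length-1, 0-based half-open interval
#' (`start = pos - 1`, `end = pos`), written in genomic order after a
#' `track` header line.
#'
#' @param values Named numeric vector keyed by probe id.
#' @param manifest Probe manifest covering every named probe.
#' @param path Output file path.
#' @param name Track name written into the header.
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(values, manifest, path, name = "methylrun") {
  stopifnot(is.numeric(values))
  probes <- names(values)
  if (length(values) && is.null(probes)) stop("'values' must be named by probe id")
  missing <- setdiff(probes, manifest$probe_id)
  if (length(missing)) {
    stop("probe(s) absent from manifest: ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  header <- sprintf('track type=bedGraph name="%s"', name)
  m <- manifest[match(probes, manifest$probe_id), , drop = FALSE]
  ord <- order(chrom_rank(m$chr), m$pos)
  lines <- c(header,
             if (length(values)) {
               paste(m$chr[ord], m$pos[ord] - 1L, m$pos[ord],
                     format(unname(values)[ord], trim = TRUE, scientific = FALSE),
                     sep = "\t")
             })
  writeLines(lines, path)
  invisible(path)
}

#' Minimal bedGraph reader
#'
#' Parses the tracks written by [export_bedgraph()] (skipping `track`
#' header lines) back into a `data.frame` of intervals and values.
#'
#' @param path Path to a bedGraph file.
#' @return A `data.frame` with columns `chr`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#|browser)", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chr = character(), start = integer(),
                      end = integer(), value = numeric()))
  }
  parts <- strsplit(lines, "[ \t]+")
  data.frame(chr = vapply(parts, `[[`, "", 1L),
             start = as.integer(vapply(parts, `[[`, "", 2L)),
             end = as.integer(vapply(parts, `[[`, "", 3L)),
             value = as.numeric(vapply(parts, `[[`, "", 4L)))
}

#' Export DMRs as BED6
#'
#' 0-based half-open intervals; `name` carries the direction, `score` is
#' `1000 * |mean delta-beta|` capped at 1000.
#'
#' @param dmrs DMR table from [find_dmrs()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_dmr_bed <- function(dmrs, path) {
  lines <- if (nrow(dmrs)) {
    paste(dmrs$chr, dmrs$start - 1L, dmrs$end, dmrs$direction,
          pmin(1000L, round(1000 * abs(dmrs$mean_delta_beta))), ".",
          sep = "\t")
  } else character()
  writeLines(lines, path)
  invisible(path)
}

## evaluate `expr` under a fixed local RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
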