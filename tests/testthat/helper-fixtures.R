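## Small in-code fixtures shared across test files.

## minimal manifest: n probes on one chromosome, evenly spaced
toy_manifest <- function(n, chr = "chr1", start = 1000L, step = 100L,
                         feature = "Body", island = "OpenSea", gene = NA) {
  data.frame(probe_id = sprintf("p%03d", seq_len(n)), chr = chr,
             pos = start + step * (seq_len(n) - 1L), strand = "+",
             gene = gene, feature = feature, island = island,
             stringsAsFactors = FALSE)
}

## a differential table with given delta (and optional fdr), minimal columns
toy_diff <- function(probe_id, delta, fdr = rep(0.01, length(delta)),
                     p = fdr) {
  n <- length(delta)
  data.frame(probe_id = probe_id, mean_a = rep(0.5, n), mean_b = 0.5 + delta,
             delta_beta = delta, t_stat = rep(NA_real_, n),
             df = rep(NA_real_, n), p_value = p, fdr = fdr,
             n_a = rep(3L, n), n_b = rep(3L, n), stringsAsFactors = FALSE)
}

## the 27-patient clinical sheet shipped with the package
cohort27 <- function() {
  read_sample_sheet(system.file("extdata", "hcc_cohort27.csv",
                                package = "methylrun"))
}

## random manifest + delta track for DMR oracle comparisons
random_dmr_instance <- function(n, n_chr = 2L) {
  chr <- sort(sample(paste0("chr", seq_len(n_chr)), n, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n), chr), function(i) {
    sort(sample.int(n * 50L, length(i)))
  }), use.names = FALSE)
  manifest <- data.frame(probe_id = sprintf("r%04d", seq_len(n)),
                         chr = sort(chr), pos = pos, strand = "+",
                         gene = NA, feature = "Body", island = "OpenSea",
                         stringsAsFactors = FALSE)
  delta <- rnorm(n, 0, 0.15)
  delta[runif(n) < 0.05] <- NA           # some probes filtered upstream
  delta[runif(n) < 0.10] <- 0            # and some flat ones
  fdr <- runif(n)
  list(manifest = manifest,
       diff = toy_diff(manifest$probe_id[!is.na(delta)],
                       delta[!is.na(delta)], fdr = fdr[!is.na(delta)]))
}
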