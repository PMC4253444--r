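## Independent oracles used to check the package implementations.

## literal Benjamini-Hochberg step-up: for each i,
## fdr_i = min over { j : p_(j) >= p_i } of p_(j) * m / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  ps <- sort(p)
  cand <- ps * m / seq_len(m)
  vapply(p, function(pi) {
    min(1, min(cand[ps >= pi]))
  }, numeric(1))
}

## straightforward scan for maximal sign-consistent qualifying runs,
## written independently of the rle-based implementation
dmr_oracle <- function(manifest, diff, min_run = 10L, delta_min = 0.1,
                       require_fdr = FALSE, fdr_max = 0.05, max_gap = NULL) {
  m <- manifest[order(chrom_rank_oracle(manifest$chr), manifest$pos), ]
  delta <- diff$delta_beta[match(m$probe_id, diff$probe_id)]
  fdr <- diff$fdr[match(m$probe_id, diff$probe_id)]
  ok <- function(i) {
    if (is.na(delta[i]) || abs(delta[i]) <= delta_min) return(FALSE)
    if (require_fdr && (is.na(fdr[i]) || fdr[i] >= fdr_max)) return(FALSE)
    TRUE
  }
  out <- list()
  i <- 1L
  n <- nrow(m)
  while (i <= n) {
    if (!ok(i)) { i <- i + 1L; next }
    j <- i
    while (j < n && m$chr[j + 1L] == m$chr[i] && ok(j + 1L) &&
           sign(delta[j + 1L]) == sign(delta[i]) &&
           (is.null(max_gap) || m$pos[j + 1L] - m$pos[j] <= max_gap)) {
      j <- j + 1L
    }
    if (j - i + 1L >= min_run) {
      out[[length(out) + 1L]] <- data.frame(
        chr = m$chr[i], start = m$pos[i], end = m$pos[j],
        n_cpgs = j - i + 1L,
        direction = if (delta[i] > 0) "hyper" else "hypo",
        mean_delta_beta = mean(delta[i:j]),
        probes = I(list(m$probe_id[i:j])),
        stringsAsFactors = FALSE)
    }
    i <- j + 1L
  }
  if (!length(out)) {
    return(data.frame(chr = character(), start = integer(), end = integer(),
                      n_cpgs = integer(), direction = character(),
                      mean_delta_beta = numeric(), probes = I(list())))
  }
  do.call(rbind, out)
}

chrom_rank_oracle <- function(chr) {
  num <- suppressWarnings(as.integer(sub("^chr", "", chr)))
  ifelse(is.na(num), 1000L, num)
}

## hypergeometric pmf from binomial coefficients (no dhyper), and the
## minlike two-sided sum over the support
fisher_oracle_p <- function(a, b, cc, d) {
  r1 <- a + b; r2 <- cc + d; k <- a + cc; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || k == 0 || k == n) return(1)
  support <- max(0, k - r2):min(r1, k)
  pmf <- exp(lchoose(r1, support) + lchoose(r2, k - support) - lchoose(n, k))
  obs <- pmf[support == a]
  min(1, sum(pmf[pmf <= obs * (1 + 1e-7)]))
}
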