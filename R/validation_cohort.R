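## Clinical-cohort cross-tabulation and Fisher's-exact comparison of
## bisulfite clone tables.

## round half-up to `digits` decimals (rendering convention of clinical
## tables; base round() is half-even)
round_half_up <- function(x, digits = 2L) {
  floor(x * 10^digits + 0.5 + 1e-9) / 10^digits
}

#' Cross-tabulate clinical features by etiology
#'
#' For each requested feature, counts each observed criterion within every
#' etiology column and a Total column, with percentages (denominator: the
#' column's total sample count) rounded half-up to 2 decimals.
#'
#' @param sheet Sample sheet `data.frame`.
#' @param features Column names to tabulate.
#' @return A long `data.frame`: `feature`, `criterion`, `group` (etiology
#'   or `"Total"`), `n`, `pct`.
#' @export
summarize_clinical <- function(sheet, features) {
  miss <- setdiff(features, names(sheet))
  if (length(miss)) stop("feature(s) not in sample sheet: ",
                         paste(miss, collapse = ", "))
  groups <- intersect(etiologies(), unique(sheet$etiology))
  col_n <- c(stats::setNames(vapply(groups, function(g) sum(sheet$etiology == g),
                                    integer(1)), groups),
             Total = nrow(sheet))
  rows <- list()
  for (f in features) {
    vals <- sheet[[f]]
    if (all(is.na(vals))) stop("feature '", f, "' has no observed values")
    crits <- sort(unique(vals[!is.na(vals)]))
    for (cr in crits) {
      for (g in c(groups, "Total")) {
        in_g <- if (g == "Total") rep(TRUE, nrow(sheet)) else sheet$etiology == g
        n <- sum(in_g & !is.na(vals) & vals == cr)
        rows[[length(rows) + 1L]] <-
          data.frame(feature = f, criterion = as.character(cr), group = g,
                     n = n, pct = round_half_up(100 * n / col_n[[g]], 2L),
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percent methylation of a clone table
#'
#' @param table Binary (0/1) matrix, clones x CpGs.
#' @return Fraction of methylated calls.
#' @export
clone_percent_methylation <- function(table) {
  if (!length(table)) stop("empty clone table")
  if (!all(table %in% c(0L, 1L))) stop("clone table entries must be 0 or 1")
  mean(table)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p by hypergeometric enumeration with the standard "minlike"
#' two-sided rule (sum of probabilities of tables, under fixed margins, no
#' more likely than the observed one, with a `1 + 1e-7` relative tie
#' tolerance).  The odds ratio is the sample OR, with the Haldane 0.5
#' correction applied when any cell is zero.
#'
#' @param x 2x2 integer matrix `rbind(c(a, b), c(c, d))`: rows are groups,
#'   columns (methylated, unmethylated) counts.
#' @return List with `odds_ratio` and `p_value`.
#' @export
fisher_exact_2x2 <- function(x) {
  stopifnot(is.matrix(x), all(dim(x) == 2L), all(x >= 0), all(is.finite(x)))
  a <- x[1, 1]; b <- x[1, 2]; cc <- x[2, 1]; d <- x[2, 2]
  or <- if (any(x == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    (a * d) / (b * cc)
  }
  r1 <- a + b; r2 <- cc + d; k <- a + cc
  p <- if (r1 == 0 || r2 == 0 || k == 0 || k == r1 + r2) {
    1  # a degenerate margin admits a single table
  } else {
    support <- max(0L, k - r2):min(r1, k)
    dens <- stats::dhyper(support, r1, r2, k)
    obs <- stats::dhyper(a, r1, r2, k)
    min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  }
  list(odds_ratio = or, p_value = p)
}

#' Fisher comparison of two bisulfite clone tables
#'
#' Collapses each clone table to (methylated, unmethylated) totals and
#' applies [fisher_exact_2x2()].
#'
#' @param table_a,table_b Binary clone matrices (clones x CpGs).
#' @return List with `odds_ratio`, `p_value` and the 2x2 `table`.
#' @export
fisher_compare <- function(table_a, table_b) {
  for (tb in list(table_a, table_b)) {
    if (!length(tb)) stop("empty clone table")
    if (!all(tb %in% c(0L, 1L))) stop("clone table entries must be 0 or 1")
  }
  x <- rbind(a = c(meth = sum(table_a), unmeth = sum(table_a == 0)),
             b = c(meth = sum(table_b), unmeth = sum(table_b == 0)))
  res <- fisher_exact_2x2(x)
  c(res, list(table = x))
}
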