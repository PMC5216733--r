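# Paired differential expression with signed fold change and FDR.

#' Paired t-test for one feature
#'
#' Tests tumor minus control log2 differences across matched patients:
#' `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1` degrees of freedom, two-sided.
#' Incomplete patient pairs (missing in either condition) are excluded.
#'
#' @param set A [paired_expression_set()].
#' @param symbol Feature symbol to test.
#' @return A list with `mean_log2_diff`, `t_stat`, `p_value`, `n_pairs`, and a
#'   `degenerate` flag (zero variance of the differences with nonzero mean, in
#'   which case `p_value` is reported as 0).
#' @export
paired_t <- function(set, symbol) {
  stopifnot(inherits(set, "paired_expression_set"))
  i <- match(symbol, set$symbols)
  if (is.na(i)) stopf("unknown symbol: %s", symbol)
  d <- set$tumor[i, ] - set$control[i, ]
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 3) stopf("fewer than 3 complete pairs for %s", symbol)
  paired_t_stats(mean(d), sd(d), n)
}

paired_t_stats <- function(m, s, n) {
  if (s == 0) {
    if (m == 0) {
      list(mean_log2_diff = 0, t_stat = 0, p_value = 1,
           n_pairs = n, degenerate = FALSE)
    } else {
      list(mean_log2_diff = m, t_stat = sign(m) * Inf, p_value = 0,
           n_pairs = n, degenerate = TRUE)
    }
  } else {
    t <- m / (s / sqrt(n))
    list(mean_log2_diff = m, t_stat = t,
         p_value = 2 * pt(-abs(t), df = n - 1),
         n_pairs = n, degenerate = FALSE)
  }
}

#' Signed fold change from a log2 difference
#'
#' Converts a log2 ratio to the signed linear convention in which
#' down-regulation is reported as a negative reciprocal: `2^x` for `x >= 0` and
#' `-2^-x` for `x < 0`, so `|signed_fc| >= 1` always (log2 shift -2.766 maps to
#' about -6.80).
#'
#' @param mean_log2_diff Numeric vector of log2 differences (tumor - control).
#' @return Numeric vector of signed fold changes.
#' @export
signed_fold_change <- function(mean_log2_diff) {
  stopifnot(is.numeric(mean_log2_diff))
  ifelse(mean_log2_diff >= 0, 2^mean_log2_diff, -(2^(-mean_log2_diff)))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment `min over j >= i of p_(j) * m / j`, clipped to 1 and
#' returned in input order.
#'
#' @param p_values Numeric vector of p-values in \code{[0, 1]}.
#' @return Adjusted FDR values in input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Paired differential expression table
#'
#' Runs the paired t-test on every feature, converts mean log2 differences to
#' signed fold changes, adjusts p-values by Benjamini-Hochberg, and assigns a
#' direction with [de_filter()]. Features with fewer than 3 complete pairs are
#' skipped with a warning.
#'
#' @param set A [paired_expression_set()].
#' @param fc_cut Signed fold-change cutoff (default 1.5).
#' @param fdr_cut FDR cutoff (default 0.05).
#' @return A data.frame with columns `symbol`, `n_pairs`, `mean_log2_diff`,
#'   `signed_fc`, `t_stat`, `p_value`, `fdr`, `degenerate`, `direction`.
#' @export
diff_expr <- function(set, fc_cut = 1.5, fdr_cut = 0.05) {
  stopifnot(inherits(set, "paired_expression_set"))
  d <- set$tumor - set$control
  n <- rowSums(!is.na(d))
  skip <- n < 3
  if (any(skip)) {
    warnf("skipping %d feature(s) with fewer than 3 complete pairs",
          sum(skip))
  }
  keep <- which(!skip)
  m <- rowMeans(d, na.rm = TRUE)[keep]
  s <- apply(d[keep, , drop = FALSE], 1, sd, na.rm = TRUE)
  n <- n[keep]

  degen <- s == 0 & m != 0
  t_stat <- ifelse(s == 0, ifelse(m == 0, 0, sign(m) * Inf),
                   m / (s / sqrt(n)))
  p <- ifelse(s == 0, ifelse(m == 0, 1, 0),
              2 * pt(-abs(t_stat), df = n - 1))

  rec <- data.frame(
    symbol = set$symbols[keep], n_pairs = as.integer(n),
    mean_log2_diff = m, signed_fc = signed_fold_change(m),
    t_stat = t_stat, p_value = p, fdr = benjamini_hochberg(p),
    degenerate = degen, stringsAsFactors = FALSE
  )
  rownames(rec) <- NULL
  de_filter(rec, fc_cut = fc_cut, fdr_cut = fdr_cut)
}

#' Assign differential-expression direction
#'
#' A feature is `up` if its signed fold change is at least `fc_cut` and its
#' FDR at most `fdr_cut`; `down` if the signed fold change is at most
#' `-fc_cut` at the same FDR; otherwise `ns`.
#'
#' @param records A data.frame with `signed_fc` and `fdr` columns.
#' @param fc_cut Signed fold-change cutoff (default 1.5).
#' @param fdr_cut FDR cutoff (default 0.05).
#' @return `records` with a `direction` factor column (`up`/`down`/`ns`).
#' @export
de_filter <- function(records, fc_cut = 1.5, fdr_cut = 0.05) {
  stopifnot(is.data.frame(records),
            all(c("signed_fc", "fdr") %in% names(records)))
  dir <- rep("ns", nrow(records))
  dir[records$signed_fc >= fc_cut & records$fdr <= fdr_cut] <- "up"
  dir[records$signed_fc <= -fc_cut & records$fdr <= fdr_cut] <- "down"
  records$direction <- factor(dir, levels = c("up", "down", "ns"))
  records
}

write_de_tsv <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
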