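# Candidate clock-targeting miRNA ranking and the small validation statistics:
# gene-miRNA inverse correlation, 2^-ddCt relative quantification, median-split
# chi-squared association, and microsatellite-instability calls.

#' Rank candidate clock-targeting miRNAs
#'
#' A miRNA is eligible iff it targets at least one clock gene and is
#' differentially expressed (direction != ns). Eligible miRNAs are scored by
#' `w1 * |log2FC| + w2 * lost_edge_fraction + w3 * hub_delta`, where
#' `lost_edge_fraction` is the fraction of the node's control-network edges
#' absent from the tumor network (0 when the control degree is 0) and
#' `hub_delta` is the absolute change in degree centrality between conditions.
#' The score formula makes a qualitative "expression plus topology" selection
#' explicit and tunable; the default weights (1, 1, 1) are deliberately
#' neutral. Ties are broken by `|log2FC|` (descending), then symbol.
#'
#' @param de_table DE table from [diff_expr()].
#' @param partition [partition_networks()] output from the same run.
#' @param targets A [target_map()].
#' @param topo_control,topo_tumor [node_metrics()] tables for the two
#'   condition networks.
#' @param weights Nonnegative numeric vector of length 3.
#' @return A data.frame of eligible candidates with the score components and
#'   `rank` (empty when nothing is eligible).
#' @export
rank_candidates <- function(de_table, partition, targets,
                            topo_control, topo_tumor, weights = c(1, 1, 1)) {
  if (length(weights) != 3 || !is.numeric(weights) || any(weights < 0)) {
    stopf("weights must be 3 nonnegative numbers")
  }
  stopifnot(inherits(partition, "edge_partition"),
            inherits(targets, "target_map"))
  eligible <- de_table$symbol %in% names(targets) &
    de_table$direction != "ns"
  cand <- de_table[eligible, c("symbol", "mean_log2_diff", "signed_fc",
                               "direction"), drop = FALSE]
  if (nrow(cand) == 0) {
    cand$abs_log2fc <- numeric(0)
    cand$lost_edge_fraction <- numeric(0)
    cand$hub_delta <- numeric(0)
    cand$score <- numeric(0)
    cand$rank <- integer(0)
    return(cand)
  }

  incident <- function(df, sym) {
    if (nrow(df) == 0) return(0L)
    sum(df$symbol_a == sym | df$symbol_b == sym)
  }
  ctl_sets <- partition[c("common", "sign_flip", "control_exclusive")]
  cand$abs_log2fc <- abs(cand$mean_log2_diff)
  cand$lost_edge_fraction <- vapply(cand$symbol, function(sym) {
    ctl_deg <- sum(vapply(ctl_sets, incident, 0L, sym = sym))
    if (ctl_deg == 0) return(0)
    incident(partition$control_exclusive, sym) / ctl_deg
  }, 0)
  dc <- function(topo, sym) {
    i <- match(sym, topo$node)
    ifelse(is.na(i), 0, topo$degree_centrality[i])
  }
  cand$hub_delta <- abs(vapply(cand$symbol, dc, 0, topo = topo_control) -
                          vapply(cand$symbol, dc, 0, topo = topo_tumor))
  cand$score <- weights[1] * cand$abs_log2fc +
    weights[2] * cand$lost_edge_fraction +
    weights[3] * cand$hub_delta
  ord <- order(-cand$score, -cand$abs_log2fc, cand$symbol)
  cand <- cand[ord, , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  cand
}

#' Gene-miRNA expression correlation
#'
#' Pearson correlation (with the small-sample t-based p-value) between a gene's
#' and a miRNA's expression across samples; used to test inverse
#' miRNA-target coupling.
#'
#' @param gene_values,mirna_values Numeric vectors of equal length.
#' @param min_n Minimum complete pairs (default 5).
#' @return As [pearson_test()].
#' @export
gene_mirna_correlation <- function(gene_values, mirna_values, min_n = 5) {
  pearson_test(gene_values, mirna_values, min_n = min_n)
}

#' Delta-Ct from raw cycle thresholds
#'
#' `mean(ct_target) - mean(ct_reference)`: the target gene's average cycle
#' threshold minus the reference (housekeeping) gene's.
#'
#' @param ct_target,ct_reference Numeric Ct values in (0, 45).
#' @return The delta-Ct value.
#' @export
delta_ct <- function(ct_target, ct_reference) {
  ct <- c(ct_target, ct_reference)
  if (any(!is.finite(ct)) || any(ct <= 0 | ct >= 45)) {
    stopf("Ct values must lie in (0, 45)")
  }
  mean(ct_target) - mean(ct_reference)
}

#' Relative quantification by 2^-ddCt
#'
#' Two sign conventions are exposed. `"paper"` uses
#' `ddCt = dCt(calibrator) - dCt(target)` and returns `2^-ddCt`; `"livak"`
#' uses `ddCt = dCt(target) - dCt(calibrator)`. The two conventions are exact
#' reciprocals for all inputs.
#'
#' @param delta_ct_calibrator,delta_ct_target Delta-Ct values (see
#'   [delta_ct()]).
#' @param convention `"paper"` (default) or `"livak"`.
#' @return The relative quantity.
#' @export
ddct <- function(delta_ct_calibrator, delta_ct_target,
                 convention = c("paper", "livak")) {
  convention <- match.arg(convention)
  dd <- switch(convention,
               paper = delta_ct_calibrator - delta_ct_target,
               livak = delta_ct_target - delta_ct_calibrator)
  2^(-dd)
}

#' Ct ratio (reference Ct over target Ct)
#'
#' An alternative per-sample summary sometimes reported instead of 2^-ddCt:
#' the housekeeping gene's average Ct divided by the target's average Ct.
#'
#' @inheritParams delta_ct
#' @return The ratio `mean(ct_reference) / mean(ct_target)`.
#' @export
ct_ratio <- function(ct_target, ct_reference) {
  ct <- c(ct_target, ct_reference)
  if (any(!is.finite(ct)) || any(ct <= 0 | ct >= 45)) {
    stopf("Ct values must lie in (0, 45)")
  }
  mean(ct_reference) / mean(ct_target)
}

#' Median-split association with a phenotype
#'
#' Splits subjects into low (value <= median, ties to low) and high expressors
#' and tests association with a categorical phenotype by Pearson's chi-squared
#' test without continuity correction (a flag enables the Yates correction).
#' Expected counts below 5 set a warning flag on the result.
#'
#' @param values Numeric expression values, one per subject.
#' @param phenotype_labels Categorical phenotype, same length.
#' @param correct Apply the continuity correction (default `FALSE`).
#' @return A list with `table` (2 x k contingency), `chi2`, `df`, `p_value`,
#'   `low_expected` flag, and `median`.
#' @export
median_split_association <- function(values, phenotype_labels,
                                     correct = FALSE) {
  stopifnot(length(values) == length(phenotype_labels))
  if (length(values) < 4) stopf("need at least 4 subjects")
  phen <- factor(phenotype_labels)
  if (nlevels(phen) < 2) stopf("need at least 2 phenotype categories")
  med <- median(values)
  grp <- factor(ifelse(values <= med, "low", "high"),
                levels = c("low", "high"))
  tab <- table(expression = grp, phenotype = phen)
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  list(table = tab, chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, low_expected = any(ht$expected < 5),
       median = med)
}

#' Microsatellite-instability call from the Bethesda five-marker panel
#'
#' Instability in four or more of the five markers is MSI-H, no instability is
#' MSS, and intermediate counts are MSI-L (counts of 1 or 3 are interpolated
#' between the stated anchors of 2 and are flagged).
#'
#' @param markers_unstable Count of unstable markers, 0 to 5.
#' @return A list with `markers_unstable`, `call` (`"MSI-H"`, `"MSI-L"`,
#'   `"MSS"`) and `interpolated`.
#' @export
msi_classify <- function(markers_unstable) {
  if (!is_count(markers_unstable) || markers_unstable > 5) {
    stopf("markers_unstable must be an integer in 0..5")
  }
  k <- as.integer(markers_unstable)
  call <- if (k >= 4) "MSI-H" else if (k >= 1) "MSI-L" else "MSS"
  list(markers_unstable = k, call = call, interpolated = k %in% c(1L, 3L))
}
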