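# Per-condition Pearson correlation networks with magnitude and significance
# filtering. p-values come from the exact small-sample t transform
# t = r * sqrt(n - 2) / sqrt(1 - r^2) on n - 2 degrees of freedom (not the
# Fisher z approximation); missing values are handled pairwise-complete with
# the complete-pair count recorded per edge.

#' Pearson correlation with small-sample significance
#'
#' Pairwise-complete Pearson r with a two-sided p-value from the t transform on
#' `n - 2` degrees of freedom; `r = +/-1` is reported with `p = 0`. Pairs with
#' fewer than `min_n` complete observations, or with a constant vector, are not
#' testable: `r` and `p_value` are `NA` with the reason recorded.
#'
#' @param x,y Numeric vectors of equal length.
#' @param min_n Minimum complete observations (default 5).
#' @return A list with `r`, `p_value`, `n_used`, and `reason` (`NA` when the
#'   pair was testable).
#' @export
pearson_test <- function(x, y, min_n = 5) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_n) {
    return(list(r = NA_real_, p_value = NA_real_, n_used = n,
                reason = "too_few_complete_pairs"))
  }
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n_used = n,
                reason = "constant_vector"))
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  list(r = r, p_value = pearson_p(r, n), n_used = n, reason = NA_character_)
}

# Two-sided p for Pearson r at n complete observations.
pearson_p <- function(r, n) {
  p <- ifelse(abs(r) >= 1, 0, {
    t <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
    2 * pt(-abs(t), df = n - 2)
  })
  p
}

#' All-pairs correlation table for one condition
#'
#' Evaluates every unordered feature pair (upper triangle) with
#' pairwise-complete Pearson correlation and the t-transform p-value. This is
#' the full unfiltered table; [build_network()] applies the |r| and
#' significance filter on top of it.
#'
#' @param mat Numeric matrix, features x samples, with feature rownames.
#' @param min_n Minimum complete observations per pair (default 5).
#' @return A data.frame with columns `symbol_a`, `symbol_b` (canonical order),
#'   `r`, `p_value`, `n_used`, `sign`, `reason`.
#' @export
correlation_table <- function(mat, min_n = 5) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  f <- nrow(mat)
  if (f < 2) stopf("need at least 2 features")
  obs <- !is.na(mat)
  n_mat <- tcrossprod(obs * 1)
  suppressWarnings(r_mat <- cor(t(mat), use = "pairwise.complete.obs"))

  idx <- which(upper.tri(r_mat), arr.ind = TRUE)
  sy <- rownames(mat)
  df <- data.frame(
    symbol_a = sy[idx[, 1]], symbol_b = sy[idx[, 2]],
    r = r_mat[idx], n_used = as.integer(n_mat[idx]),
    stringsAsFactors = FALSE
  )
  df$reason <- NA_character_
  df$reason[df$n_used < min_n] <- "too_few_complete_pairs"
  df$reason[df$n_used >= min_n & is.na(df$r)] <- "constant_vector"
  testable <- is.na(df$reason)
  df$r[!testable] <- NA_real_
  df$p_value <- NA_real_
  df$p_value[testable] <- pearson_p(df$r[testable], df$n_used[testable])
  df$sign <- ifelse(is.na(df$r), NA_character_, ifelse(df$r >= 0, "+", "-"))
  df <- df[, c("symbol_a", "symbol_b", "r", "p_value", "n_used",
               "sign", "reason")]
  canonicalize_pairs(df)
}

#' Construct a correlation network object
#'
#' Low-level constructor used by [build_network()] and by readers of exported
#' edge tables.
#'
#' @param condition `"tumor"` or `"control"`.
#' @param edges Data.frame with at least `symbol_a`, `symbol_b`, `r` columns
#'   (`p_value`, `n_used` optional); `sign` is derived from `r` if absent.
#' @param nodes Character vector of node symbols (defaults to edge endpoints).
#' @param r_cut,alpha The thresholds the edges were filtered at.
#' @return A `correlation_network` object.
#' @export
correlation_network <- function(condition, edges, nodes = NULL,
                                r_cut = 0.8, alpha = 0.05) {
  condition <- match.arg(condition, c("tumor", "control"))
  stopifnot(is.data.frame(edges),
            all(c("symbol_a", "symbol_b") %in% names(edges)))
  if (is.null(edges$sign)) {
    stopifnot(!is.null(edges$r))
    edges$sign <- as.character(ifelse(edges$r >= 0, "+", "-"))
  }
  if (any(edges$symbol_a == edges$symbol_b)) stopf("self-loop edge")
  edges <- canonicalize_pairs(edges)
  if (anyDuplicated(pair_key(edges$symbol_a, edges$symbol_b))) {
    stopf("duplicate edge for an unordered pair")
  }
  nodes <- sort(unique(c(nodes, edges$symbol_a, edges$symbol_b)))
  node_attrs <- data.frame(
    symbol = nodes,
    de_direction = rep("ns", length(nodes)),
    clock_target = rep(FALSE, length(nodes)),
    cross_dataset = rep(FALSE, length(nodes)),
    stringsAsFactors = FALSE
  )
  structure(
    list(condition = condition, edges = edges, node_attrs = node_attrs,
         params = list(r_cut = r_cut, alpha = alpha)),
    class = "correlation_network"
  )
}

#' Build the filtered correlation network for one condition
#'
#' Evaluates all feature pairs and retains an edge iff `|r| >= r_cut` and
#' `p <= alpha` (raw p by default, matching the published filtering rule; an
#' optional Benjamini-Hochberg mode adjusts edge p-values first). Presets used
#' in practice are `r_cut = 0.8` (main analysis) and `r_cut = 0.6`.
#'
#' @param mat Numeric matrix for one condition (features x samples, rownames =
#'   symbols), or a [paired_expression_set()] together with `condition`.
#' @param condition `"tumor"` or `"control"`.
#' @param r_cut Correlation magnitude threshold in (0, 1); default 0.8.
#' @param alpha Significance threshold on the edge p-value; default 0.05.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param min_n Minimum complete observations per pair (default 5).
#' @return A `correlation_network`; all nodes of the matrix are kept in
#'   `node_attrs` even when isolated after filtering.
#' @export
build_network <- function(mat, condition, r_cut = 0.8, alpha = 0.05,
                          adjust = c("none", "BH"), min_n = 5) {
  if (inherits(mat, "paired_expression_set")) {
    mat <- mat[[match.arg(condition, c("tumor", "control"))]]
  }
  adjust <- match.arg(adjust)
  if (!(r_cut > 0 && r_cut < 1)) stopf("r_cut must be in (0, 1)")
  tab <- correlation_table(mat, min_n = min_n)
  p <- tab$p_value
  if (adjust == "BH") {
    ok <- !is.na(p)
    p[ok] <- benjamini_hochberg(p[ok])
  }
  keep <- !is.na(tab$r) & abs(tab$r) >= r_cut & p <= alpha
  edges <- tab[keep, c("symbol_a", "symbol_b", "r", "p_value",
                       "n_used", "sign")]
  rownames(edges) <- NULL
  net <- correlation_network(condition, edges, nodes = rownames(mat),
                             r_cut = r_cut, alpha = alpha)
  net$params$adjust <- adjust
  net$params$min_n <- min_n
  net
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("Correlation network (%s): %d nodes, %d edges (|r| >= %g, p <= %g)\n",
              x$condition, nrow(x$node_attrs), nrow(x$edges),
              x$params$r_cut, x$params$alpha))
  if (nrow(x$edges) > 0) {
    cat(sprintf("  positive edges: %d, negative edges: %d\n",
                sum(x$edges$sign == "+"), sum(x$edges$sign == "-")))
  }
  invisible(x)
}

#' Annotate network nodes with DE status, clock-target and cross-dataset flags
#'
#' @param net A `correlation_network`.
#' @param de_table Optional DE table from [diff_expr()].
#' @param targets Optional [target_map()]; nodes with at least one clock-gene
#'   target are flagged.
#' @param cross_symbols Optional character vector of symbols present in a
#'   second, independently analyzed dataset; absent, the flag stays `FALSE`.
#' @return The network with `node_attrs` filled in.
#' @export
annotate_network <- function(net, de_table = NULL, targets = NULL,
                             cross_symbols = NULL) {
  stopifnot(inherits(net, "correlation_network"))
  na <- net$node_attrs
  if (!is.null(de_table)) {
    i <- match(na$symbol, de_table$symbol)
    na$de_direction <- ifelse(is.na(i), "ns",
                              as.character(de_table$direction[i]))
  }
  if (!is.null(targets)) {
    na$clock_target <- na$symbol %in% names(targets)
  }
  if (!is.null(cross_symbols)) {
    na$cross_dataset <- na$symbol %in% cross_symbols
  }
  net$node_attrs <- na
  net
}
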