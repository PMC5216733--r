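# Edge-set algebra between condition networks, miRNA symbol resolution against
# a miRBase-style alias table, and clock-controller tagging from a target map.

#' Partition tumor and control network edges by coherence
#'
#' A pair present (post-filter) in both networks with the same correlation sign
#' is coherently correlated ("common"); present in both with opposite signs it
#' is a sign flip (a distinct category, not counted as common); otherwise it is
#' exclusive to the network containing it. The four sets are disjoint and cover
#' the union of both edge sets.
#'
#' @param tumor,control `correlation_network` objects built with the same
#'   `r_cut` and `alpha` (a threshold mismatch is an error).
#' @return An `edge_partition`: data.frames `common`, `sign_flip`,
#'   `tumor_exclusive`, `control_exclusive` plus `venn_counts`.
#' @export
partition_networks <- function(tumor, control) {
  stopifnot(inherits(tumor, "correlation_network"),
            inherits(control, "correlation_network"))
  if (!isTRUE(all.equal(tumor$params$r_cut, control$params$r_cut)) ||
      !isTRUE(all.equal(tumor$params$alpha, control$params$alpha))) {
    stopf("networks were built with different thresholds")
  }
  tk <- pair_key(tumor$edges$symbol_a, tumor$edges$symbol_b)
  ck <- pair_key(control$edges$symbol_a, control$edges$symbol_b)
  ts <- setNames(tumor$edges$sign, tk)
  cs <- setNames(control$edges$sign, ck)

  both <- intersect(tk, ck)
  same <- both[ts[both] == cs[both]]
  flip <- setdiff(both, same)

  take <- function(edges, keys, keep, extra = NULL) {
    df <- edges[keys %in% keep,
                c("symbol_a", "symbol_b", "sign"), drop = FALSE]
    canonicalize_pairs(df)
  }
  common <- take(tumor$edges, tk, same)
  common$r_tumor <- tumor$edges$r[match(pair_key(common$symbol_a, common$symbol_b), tk)]
  common$r_control <- control$edges$r[match(pair_key(common$symbol_a, common$symbol_b), ck)]
  sign_flip <- take(tumor$edges, tk, flip)
  if (nrow(sign_flip) > 0) {
    k <- pair_key(sign_flip$symbol_a, sign_flip$symbol_b)
    sign_flip$sign_tumor <- ts[k]
    sign_flip$sign_control <- cs[k]
    sign_flip$sign <- NULL
  }
  tumor_excl <- take(tumor$edges, tk, setdiff(tk, ck))
  control_excl <- take(control$edges, ck, setdiff(ck, tk))

  structure(
    list(common = common, sign_flip = sign_flip,
         tumor_exclusive = tumor_excl, control_exclusive = control_excl,
         venn_counts = c(common = nrow(common), sign_flip = nrow(sign_flip),
                         tumor_exclusive = nrow(tumor_excl),
                         control_exclusive = nrow(control_excl)),
         params = tumor$params),
    class = "edge_partition"
  )
}

#' @export
print.edge_partition <- function(x, ...) {
  cat("Edge partition (coherence Venn):\n")
  for (nm in names(x$venn_counts)) {
    cat(sprintf("  %-18s %d\n", nm, x$venn_counts[[nm]]))
  }
  invisible(x)
}

#' Load a miRBase-style alias table
#'
#' Dialect: one row per accession, `accession<TAB>alias1;alias2;...;` with the
#' most recent symbol last. Lookup is case-insensitive on the `hsa-`-prefixed
#' form.
#'
#' @param path Path to the aliases file (no header).
#' @return An `alias_table`.
#' @export
load_alias_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  acc <- vapply(parts, `[[`, "", 1)
  aliases <- lapply(parts, function(p) {
    al <- if (length(p) >= 2) strsplit(p[[2]], ";", fixed = TRUE)[[1]] else character()
    al <- trimws(al)
    al[nzchar(al)]
  })
  if (any(vapply(aliases, anyDuplicated, 0L) > 0)) {
    stopf("duplicate alias within a row")
  }
  structure(setNames(aliases, acc), class = "alias_table")
}

normalize_mirna_symbol <- function(x) {
  x <- tolower(trimws(x))
  ifelse(startsWith(x, "hsa-"), x, paste0("hsa-", x))
}

#' Resolve miRNA symbols against an alias table
#'
#' Returns the latest alias (last in its row) for any symbol found in exactly
#' one alias row. Symbols matching no row, or matching several rows ambiguously
#' (e.g. legacy names shared by -5p and -3p mature products), are kept with
#' their original names and reported via the `unresolved` attribute. Matching
#' is case-insensitive after `hsa-` prefix normalization; resolution is
#' idempotent.
#'
#' @param raw Character vector of miRNA symbols.
#' @param aliases An `alias_table` from [load_alias_table()].
#' @return Character vector of resolved symbols, with attribute `unresolved`
#'   (the input symbols kept unchanged).
#' @export
resolve_symbols <- function(raw, aliases) {
  stopifnot(inherits(aliases, "alias_table"))
  norm_rows <- lapply(aliases, normalize_mirna_symbol)
  lookup <- data.frame(
    token = unlist(norm_rows, use.names = FALSE),
    row = rep(seq_along(norm_rows), lengths(norm_rows)),
    stringsAsFactors = FALSE
  )
  out <- as.character(raw)
  unresolved <- character()
  for (i in seq_along(raw)) {
    tok <- normalize_mirna_symbol(raw[i])
    rows <- unique(lookup$row[lookup$token == tok])
    if (length(rows) == 1) {
      al <- aliases[[rows]]
      out[i] <- al[length(al)]
    } else {
      unresolved <- c(unresolved, raw[i])
    }
  }
  if (length(unresolved) > 0) {
    message("unresolved miRNA symbol(s) kept as-is: ",
            paste(unique(unresolved), collapse = ", "))
  }
  attr(out, "unresolved") <- unique(unresolved)
  out
}

#' @rdname resolve_symbols
#' @export
resolve_symbol <- function(raw, aliases) {
  stopifnot(length(raw) == 1)
  out <- resolve_symbols(raw, aliases)
  attributes(out) <- NULL
  out
}

#' Core circadian clock gene universe
#'
#' Default set of core clock oscillator genes used to restrict target maps.
#'
#' @return Character vector of gene symbols.
#' @export
clock_genes <- function() {
  c("ARNTL", "ARNTL2", "CLOCK", "NPAS2", "PER1", "PER2", "PER3",
    "CRY1", "CRY2", "NR1D1", "NR1D2", "RORA", "TIMELESS", "TIPIN",
    "CSNK1E", "SIRT1")
}

#' miRNA-to-clock-gene target map
#'
#' @param x A named list (miRNA symbol -> character vector of gene symbols) or
#'   a data.frame with `mirna` and `gene` columns.
#' @param universe Allowed gene symbols (default [clock_genes()]).
#' @return A `target_map` (named list; empty target sets are dropped).
#' @export
target_map <- function(x, universe = clock_genes()) {
  if (is.data.frame(x)) {
    stopifnot(all(c("mirna", "gene") %in% names(x)))
    x <- split(as.character(x$gene), as.character(x$mirna))
  }
  stopifnot(is.list(x), !is.null(names(x)))
  x <- lapply(x, function(g) sort(unique(as.character(g))))
  bad <- unique(unlist(x)[!(unlist(x) %in% universe)])
  if (length(bad) > 0) {
    stopf("target gene(s) outside the clock universe: %s",
          paste(bad, collapse = ", "))
  }
  x <- x[lengths(x) > 0]
  structure(x, class = "target_map")
}

#' Load a target map from TSV (columns `mirna`, `gene`, one pair per row)
#'
#' @param path Path to the TSV file.
#' @inheritParams target_map
#' @return A `target_map`.
#' @export
load_target_map <- function(path, universe = clock_genes()) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  target_map(df, universe = universe)
}

#' Tag clock-controller pairs and clock-targeting nodes
#'
#' A correlated miRNA pair is a clock-controller pair iff at least one member
#' has a validated clock-gene target; a node is flagged iff it has any target.
#'
#' @param x A `correlation_network` or an `edge_partition`.
#' @param targets A [target_map()].
#' @return `x` with a logical `clock_controller` column added to each edge
#'   table (and, for networks, the `clock_target` node flag set).
#' @export
tag_clock_controllers <- function(x, targets) {
  stopifnot(inherits(targets, "target_map"))
  has_target <- function(sym) sym %in% names(targets)
  tag_edges <- function(df) {
    if (nrow(df) == 0) {
      df$clock_controller <- logical(0)
    } else {
      df$clock_controller <- has_target(df$symbol_a) | has_target(df$symbol_b)
    }
    df
  }
  if (inherits(x, "correlation_network")) {
    x$edges <- tag_edges(x$edges)
    x$node_attrs$clock_target <- has_target(x$node_attrs$symbol)
  } else if (inherits(x, "edge_partition")) {
    for (nm in c("common", "sign_flip", "tumor_exclusive", "control_exclusive")) {
      x[[nm]] <- tag_edges(x[[nm]])
    }
  } else {
    stopf("x must be a correlation_network or edge_partition")
  }
  x
}
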