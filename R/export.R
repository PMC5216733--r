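# Deterministic plain-text exports for network viewers and downstream tools.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Export network edges as TSV
#'
#' Columns: `symbol_a`, `symbol_b`, `r`, `p_value`, `n_used`, `sign`,
#' `condition`.
#'
#' @param net A `correlation_network`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_edges_tsv <- function(net, path) {
  stopifnot(inherits(net, "correlation_network"))
  df <- net$edges
  df$condition <- net$condition
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network edge TSV written by [write_edges_tsv()]
#'
#' @param path Path to the edge TSV.
#' @param r_cut,alpha Thresholds the edges were filtered at (recorded on the
#'   object, used to validate partition compatibility).
#' @return A `correlation_network`.
#' @export
read_edges_tsv <- function(path, r_cut = 0.8, alpha = 0.05) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  cond <- if ("condition" %in% names(df) && nrow(df) > 0) {
    df$condition[1]
  } else "tumor"
  correlation_network(cond, df[setdiff(names(df), "condition")],
                      r_cut = r_cut, alpha = alpha)
}

#' Export a network in SIF format (`symbol_a corr symbol_b`)
#'
#' @inheritParams write_edges_tsv
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "correlation_network"))
  lines <- sprintf("%s\tcorr\t%s", net$edges$symbol_a, net$edges$symbol_b)
  iso <- setdiff(net$node_attrs$symbol,
                 c(net$edges$symbol_a, net$edges$symbol_b))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Export a network as GraphML with r/p/sign edge attributes
#'
#' Node attributes mirror `node_attrs` (DE direction, clock-target and
#' cross-dataset flags); edges carry `r`, `p_value` and `sign`.
#'
#' @inheritParams write_edges_tsv
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "correlation_network"))
  na <- net$node_attrs
  e <- net$edges
  head_lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="d0" for="node" attr.name="de_direction" attr.type="string"/>',
    '  <key id="d1" for="node" attr.name="clock_target" attr.type="boolean"/>',
    '  <key id="d2" for="node" attr.name="cross_dataset" attr.type="boolean"/>',
    '  <key id="e0" for="edge" attr.name="r" attr.type="double"/>',
    '  <key id="e1" for="edge" attr.name="p_value" attr.type="double"/>',
    '  <key id="e2" for="edge" attr.name="sign" attr.type="string"/>',
    sprintf('  <graph id="%s" edgedefault="undirected">',
            xml_escape(net$condition))
  )
  node_lines <- sprintf(
    '    <node id="%s"><data key="d0">%s</data><data key="d1">%s</data><data key="d2">%s</data></node>',
    xml_escape(na$symbol), xml_escape(na$de_direction),
    tolower(na$clock_target), tolower(na$cross_dataset)
  )
  edge_lines <- if (nrow(e) > 0) {
    sprintf(
      '    <edge source="%s" target="%s"><data key="e0">%.15g</data><data key="e1">%.15g</data><data key="e2">%s</data></edge>',
      xml_escape(e$symbol_a), xml_escape(e$symbol_b), e$r, e$p_value, e$sign
    )
  } else character()
  writeLines(c(head_lines, node_lines, edge_lines,
               "  </graph>", "</graphml>"), path)
  invisible(path)
}

#' Export an edge partition as JSON
#'
#' Four pair lists plus the Venn counts.
#'
#' @param partition An `edge_partition`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_partition_json <- function(partition, path) {
  stopifnot(inherits(partition, "edge_partition"))
  obj <- list(
    common = partition$common,
    sign_flip = partition$sign_flip,
    tumor_exclusive = partition$tumor_exclusive,
    control_exclusive = partition$control_exclusive,
    venn_counts = as.list(partition$venn_counts)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
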