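# End-to-end orchestration: load -> (optional) normalize -> paired DE ->
# per-condition networks -> partition -> annotation -> topology -> ranking.
# Every analysis stage is deterministic; the single config seed governs only
# synthetic-data generation, so re-running a config reproduces every artifact
# byte for byte.

#' Pipeline configuration
#'
#' @param expression Path to the expression TSV.
#' @param samplesheet Path to the sample sheet TSV.
#' @param target_map Path to the miRNA-to-clock-gene target map TSV.
#' @param aliases Optional path to a miRBase-style alias table; when given,
#'   matrix symbols are resolved before analysis.
#' @param second_expression,second_samplesheet Optional second dataset; its
#'   symbols set the cross-dataset node flag.
#' @param normalize Quantile-normalize the matrices before analysis
#'   (default `TRUE`).
#' @param r_cut Edge correlation threshold (default 0.8; 0.6 is the other
#'   common preset).
#' @param alpha Edge significance threshold (default 0.05).
#' @param fc_cut,fdr_cut DE thresholds (defaults 1.5 and 0.05).
#' @param weights Candidate-score weights (default `c(1, 1, 1)`).
#' @param seed Integer seed recorded in the run summary.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(expression, samplesheet, target_map,
                            aliases = NULL,
                            second_expression = NULL,
                            second_samplesheet = NULL,
                            normalize = TRUE,
                            r_cut = 0.8, alpha = 0.05,
                            fc_cut = 1.5, fdr_cut = 0.05,
                            weights = c(1, 1, 1), seed = 1L) {
  if (!(r_cut > 0 && r_cut < 1)) stopf("r_cut must be in (0, 1)")
  if (!(alpha > 0 && alpha <= 1)) stopf("alpha must be in (0, 1]")
  if (fc_cut < 1) stopf("fc_cut must be >= 1")
  if (!(fdr_cut > 0 && fdr_cut <= 1)) stopf("fdr_cut must be in (0, 1]")
  if (length(weights) != 3 || any(weights < 0)) {
    stopf("weights must be 3 nonnegative numbers")
  }
  structure(
    list(expression = expression, samplesheet = samplesheet,
         target_map = target_map, aliases = aliases,
         second_expression = second_expression,
         second_samplesheet = second_samplesheet,
         normalize = isTRUE(normalize),
         r_cut = r_cut, alpha = alpha, fc_cut = fc_cut, fdr_cut = fdr_cut,
         weights = as.numeric(weights), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration (flat YAML)
#'
#' @param path Path to the YAML file.
#' @return [read_pipeline_config()] returns a `pipeline_config`;
#'   [write_pipeline_config()] returns the path invisibly.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  y <- unclass(config)
  y <- y[!vapply(y, is.null, TRUE)]
  yaml::write_yaml(y, path)
  invisible(path)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(
      class = c("clocknet_stage_error", "error", "condition"),
      list(message = sprintf("pipeline stage '%s' failed: %s",
                             name, conditionMessage(e)),
           call = NULL, stage = name)
    ))
  })
}

stage_log <- function(name, ...) {
  message(sprintf("[clocknet] stage=%s %s", name, sprintf(...)))
}

#' Run the full differential co-expression pipeline
#'
#' Executes every stage and writes all artifacts (DE table, edge TSV/SIF/
#' GraphML per condition, partition JSON, topology TSVs, candidate table, run
#' summary JSON) into `out_dir`. Re-running the same config reproduces every
#' file byte-identically. A stage failure aborts with an error naming the
#' stage (condition class `clocknet_stage_error`).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The run summary, invisibly (also written as `summary.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  set <- pipeline_stage("load", {
    s <- load_paired_set(config$expression, config$samplesheet)
    stage_log("load", "features=%d patients=%d",
              length(s$symbols), length(s$patients))
    s
  })

  if (!is.null(config$aliases)) {
    set <- pipeline_stage("resolve_symbols", {
      al <- load_alias_table(config$aliases)
      resolved <- resolve_symbols(set$symbols, al)
      n_changed <- sum(resolved != set$symbols)
      stage_log("resolve_symbols", "updated=%d unresolved=%d", n_changed,
                length(attr(resolved, "unresolved")))
      paired_expression_set(as.character(resolved), set$patients,
                            set$control, set$tumor)
    })
  }

  if (config$normalize) {
    set <- pipeline_stage("normalize", {
      s <- quantile_normalize(set)
      stage_log("normalize", "columns=%d", 2 * length(s$patients))
      s
    })
  }

  de <- pipeline_stage("diff_expression", {
    d <- diff_expr(set, fc_cut = config$fc_cut, fdr_cut = config$fdr_cut)
    stage_log("diff_expression", "tested=%d up=%d down=%d", nrow(d),
              sum(d$direction == "up"), sum(d$direction == "down"))
    d
  })

  nets <- pipeline_stage("correlation_networks", {
    n <- lapply(c(control = "control", tumor = "tumor"), function(cond) {
      build_network(set[[cond]], cond, r_cut = config$r_cut,
                    alpha = config$alpha)
    })
    stage_log("correlation_networks", "edges_control=%d edges_tumor=%d",
              nrow(n$control$edges), nrow(n$tumor$edges))
    n
  })

  part <- pipeline_stage("partition", {
    p <- partition_networks(nets$tumor, nets$control)
    stage_log("partition", "common=%d sign_flip=%d tumor_excl=%d control_excl=%d",
              p$venn_counts["common"], p$venn_counts["sign_flip"],
              p$venn_counts["tumor_exclusive"],
              p$venn_counts["control_exclusive"])
    p
  })

  ann <- pipeline_stage("annotation", {
    if (is.null(config$target_map) || !file.exists(config$target_map)) {
      stopf("target map file not found: %s",
            config$target_map %||% "<missing>")
    }
    targets <- load_target_map(config$target_map)
    cross <- NULL
    if (!is.null(config$second_expression)) {
      second <- load_paired_set(config$second_expression,
                                config$second_samplesheet)
      cross <- second$symbols
    }
    nets <- lapply(nets, function(net) {
      annotate_network(tag_clock_controllers(net, targets),
                       de_table = de, targets = targets,
                       cross_symbols = cross)
    })
    part <- tag_clock_controllers(part, targets)
    stage_log("annotation", "clock_targeting_nodes=%d",
              sum(nets$control$node_attrs$clock_target))
    list(nets = nets, part = part, targets = targets)
  })
  nets <- ann$nets
  part <- ann$part

  topo <- pipeline_stage("topology", {
    t <- lapply(nets, node_metrics)
    stage_log("topology", "nodes_control=%d nodes_tumor=%d",
              nrow(t$control), nrow(t$tumor))
    t
  })

  cand <- pipeline_stage("candidates", {
    cc <- rank_candidates(de, part, ann$targets, topo$control, topo$tumor,
                          weights = config$weights)
    stage_log("candidates", "eligible=%d", nrow(cc))
    cc
  })

  pipeline_stage("export", {
    write_de_tsv(de, file.path(out_dir, "de_table.tsv"))
    for (cond in c("control", "tumor")) {
      write_edges_tsv(nets[[cond]],
                      file.path(out_dir, sprintf("edges_%s.tsv", cond)))
      write_sif(nets[[cond]],
                file.path(out_dir, sprintf("network_%s.sif", cond)))
      write_graphml(nets[[cond]],
                    file.path(out_dir, sprintf("network_%s.graphml", cond)))
      write_topology_tsv(topo[[cond]],
                         file.path(out_dir, sprintf("topology_%s.tsv", cond)))
    }
    write_partition_json(part, file.path(out_dir, "partition.json"))
    write.table(cand, file.path(out_dir, "candidates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })

  summary <- list(
    package_version = as.character(packageVersion("clocknet")),
    seed = config$seed,
    thresholds = list(r_cut = config$r_cut, alpha = config$alpha,
                      fc_cut = config$fc_cut, fdr_cut = config$fdr_cut),
    stages = list(
      features = length(set$symbols),
      patients = length(set$patients),
      de_tested = nrow(de),
      de_up = sum(de$direction == "up"),
      de_down = sum(de$direction == "down"),
      edges_control = nrow(nets$control$edges),
      edges_tumor = nrow(nets$tumor$edges),
      venn = as.list(part$venn_counts),
      clock_targeting_nodes = sum(nets$control$node_attrs$clock_target),
      candidates = nrow(cand)
    ),
    top_candidate = if (nrow(cand) > 0) cand$symbol[1] else NULL
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
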