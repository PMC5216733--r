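# Seeded synthetic matched-cohort generator with planted structure.
#
# Correlation modules use a shared latent factor per module:
#   member_i = l_i * F + sqrt(1 - |rho|) * eps_i,   l_i = +/- sqrt(|rho|)
# with standard normal F and eps, so any two members i, j have population
# correlation l_i * l_j / 1 = sign_i * sign_j * |rho| exactly. For rho < 0 the
# loadings alternate in sign, so cross-sign pairs are anti-correlated at -|rho|
# (mutual anti-correlation of a whole module at a common negative rho is not
# representable; only pairwise targets are recorded in the ground truth).

#' Configuration for the synthetic matched cohort
#'
#' Describes a cohort of `n_patients` matched tumor/control profiles over
#' `n_mirnas` miRNAs plus `clock_gene_symbols` mRNAs, with planted correlation
#' modules per condition, planted log2 expression shifts in tumor, and planted
#' miRNA-gene coupling. Defaults emulate a 14-pair matched microarray cohort.
#'
#' @param n_patients Number of matched pairs (default 14, minimum 3).
#' @param n_mirnas Number of miRNA features (default 300). Symbols are
#'   `hsa-miR-s001` ... `hsa-miR-s<n>`.
#' @param clock_gene_symbols Clock-gene mRNA features appended to the matrix
#'   (default `"TIMELESS"`).
#' @param modules_control,modules_tumor Lists of planted correlation modules,
#'   each `list(members = <symbols>, rho = <target correlation>)` with
#'   `|rho| < 1`. `modules_tumor` defaults to `modules_control` (no rewiring).
#' @param de_effects Named numeric vector of log2 shifts added to tumor rows.
#' @param coupling List of planted miRNA-gene couplings, each
#'   `list(mirna = <symbol>, gene = <symbol>, rho = <target correlation>)`,
#'   applied in both conditions.
#' @param noise_sd Per-feature standard deviation in log2 units (default 0.3).
#' @param center Baseline log2 intensity (default 8, microarray-like).
#' @param seed Integer master seed; a fixed seed makes the cohort bit-identical.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 14, n_mirnas = 300,
                             clock_gene_symbols = "TIMELESS",
                             modules_control = list(), modules_tumor = NULL,
                             de_effects = numeric(), coupling = list(),
                             noise_sd = 0.3, center = 8, seed = 1L) {
  if (!is_count(n_patients) || n_patients < 3) stopf("n_patients must be >= 3")
  if (!is_count(n_mirnas) || n_mirnas < 1) stopf("n_mirnas must be >= 1")
  if (!is.numeric(noise_sd) || noise_sd <= 0) stopf("noise_sd must be > 0")
  modules_tumor <- modules_tumor %||% modules_control
  symbols <- c(sprintf("hsa-miR-s%03d", seq_len(n_mirnas)),
               as.character(clock_gene_symbols))
  if (anyDuplicated(symbols)) stopf("duplicate symbol in config")

  check_modules <- function(mods, what) {
    seen <- character()
    for (m in mods) {
      if (!is.list(m) || is.null(m$members) || is.null(m$rho)) {
        stopf("%s: each module needs $members and $rho", what)
      }
      if (abs(m$rho) >= 1) stopf("%s: |rho| must be < 1 (got %g)", what, m$rho)
      if (anyDuplicated(m$members)) stopf("duplicate symbol in config")
      if (any(m$members %in% seen)) stopf("duplicate symbol in config")
      if (!all(m$members %in% symbols)) {
        stopf("%s: unknown member symbol(s): %s", what,
              paste(setdiff(m$members, symbols), collapse = ", "))
      }
      seen <- c(seen, m$members)
    }
  }
  check_modules(modules_control, "modules_control")
  check_modules(modules_tumor, "modules_tumor")
  if (length(de_effects) > 0) {
    if (is.null(names(de_effects)) || !all(names(de_effects) %in% symbols)) {
      stopf("de_effects must be named by known symbols")
    }
  }
  for (cp in coupling) {
    if (!all(c(cp$mirna, cp$gene) %in% symbols)) stopf("unknown coupling symbol")
    if (abs(cp$rho) >= 1) stopf("coupling |rho| must be < 1")
  }

  structure(
    list(n_patients = as.integer(n_patients), n_mirnas = as.integer(n_mirnas),
         clock_gene_symbols = as.character(clock_gene_symbols),
         symbols = symbols,
         modules_control = modules_control, modules_tumor = modules_tumor,
         de_effects = de_effects, coupling = coupling,
         noise_sd = noise_sd, center = center, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

module_pairs <- function(mods) {
  out <- data.frame(symbol_a = character(), symbol_b = character(),
                    rho = numeric(), stringsAsFactors = FALSE)
  for (m in mods) {
    k <- length(m$members)
    if (k < 2) next
    signs <- rep_len(c(1, -1), k)
    if (m$rho >= 0) signs <- rep(1, k)
    idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    out <- rbind(out, data.frame(
      symbol_a = m$members[idx[, 1]], symbol_b = m$members[idx[, 2]],
      rho = signs[idx[, 1]] * signs[idx[, 2]] * abs(m$rho),
      stringsAsFactors = FALSE
    ))
  }
  canonicalize_pairs(out)
}

simulate_condition <- function(config, mods, noise_block, module_block) {
  f <- length(config$symbols)
  p <- config$n_patients
  mat <- with_seed(block_seed(config$seed, noise_block), {
    matrix(rnorm(f * p, mean = 0, sd = 1), f, p)
  })
  with_seed(block_seed(config$seed, module_block), {
    for (m in mods) {
      k <- length(m$members)
      rho <- abs(m$rho)
      signs <- if (m$rho >= 0) rep(1, k) else rep_len(c(1, -1), k)
      fac <- rnorm(p)
      eps <- matrix(rnorm(k * p), k, p)
      rows <- match(m$members, config$symbols)
      mat[rows, ] <- signs * sqrt(rho) * rep(fac, each = k) +
        sqrt(1 - rho) * eps
    }
    mat
  })
}

#' Generate a synthetic matched cohort with known ground truth
#'
#' Simulates control and tumor log2 matrices per the configuration and returns
#' them together with the planted truth (module edges with pairwise target
#' correlations, signed fold changes, and miRNA-gene couplings). The truth is
#' emitted alongside the data and is never read by the analysis pipeline.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `set` (a [paired_expression_set()]) and
#'   `truth` (a `ground_truth` list with `true_edges_control`,
#'   `true_edges_tumor`, `true_de`, `true_coupling`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  f <- length(config$symbols)
  p <- config$n_patients

  ctl <- simulate_condition(config, config$modules_control,
                            "noise_control", "modules_control")
  tum <- simulate_condition(config, config$modules_tumor,
                            "noise_tumor", "modules_tumor")

  # Planted miRNA-gene coupling: regenerate the gene row from the miRNA's
  # standardized latent value so the population correlation is exact.
  if (length(config$coupling) > 0) {
    with_seed(block_seed(config$seed, "coupling"), {
      for (cp in config$coupling) {
        gi <- match(cp$gene, config$symbols)
        mi <- match(cp$mirna, config$symbols)
        for (cond in c("ctl", "tum")) {
          z <- get(cond)[mi, ]  # unit-variance latent by construction
          eta <- rnorm(p)
          row <- cp$rho * z + sqrt(1 - cp$rho^2) * eta
          if (cond == "ctl") ctl[gi, ] <- row else tum[gi, ] <- row
        }
      }
    })
  }

  ctl <- config$center + config$noise_sd * ctl
  tum <- config$center + config$noise_sd * tum
  if (length(config$de_effects) > 0) {
    rows <- match(names(config$de_effects), config$symbols)
    tum[rows, ] <- tum[rows, ] + config$de_effects
  }

  patients <- sprintf("P%02d", seq_len(p))
  set <- paired_expression_set(config$symbols, patients, ctl, tum)

  truth <- structure(list(
    true_edges_control = module_pairs(config$modules_control),
    true_edges_tumor = module_pairs(config$modules_tumor),
    true_de = if (length(config$de_effects) > 0) {
      setNames(signed_fold_change(as.numeric(config$de_effects)),
               names(config$de_effects))
    } else setNames(numeric(), character()),
    true_coupling = config$coupling,
    seed = config$seed
  ), class = "ground_truth")

  list(set = set, truth = truth)
}

#' Write a synthetic cohort as plain-text fixture files
#'
#' Emits the TSV dialects consumed by [load_paired_set()] (a combined
#' expression matrix and a sample sheet), the ground truth as JSON, and a
#' manifest listing every file with its dimensions. Round-trips losslessly.
#'
#' @param set A [paired_expression_set()].
#' @param truth A `ground_truth` object from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly (a list; also written to `manifest.json`).
#' @export
write_fixture <- function(set, truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tum_ids <- paste0(set$patients, "_T")
  ctl_ids <- paste0(set$patients, "_N")
  mat <- cbind(set$tumor, set$control)
  colnames(mat) <- c(tum_ids, ctl_ids)

  expr_path <- file.path(dir, "expression.tsv")
  write_expression_tsv(mat, expr_path)
  ss <- data.frame(
    sample_id = c(tum_ids, ctl_ids),
    patient_id = rep(set$patients, 2),
    tissue = rep(c("tumor", "control"), each = length(set$patients)),
    stringsAsFactors = FALSE
  )
  ss_path <- file.path(dir, "samplesheet.tsv")
  write_samplesheet_tsv(ss, ss_path)

  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(unclass(truth), truth_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  manifest <- list(
    files = list(
      expression = list(path = basename(expr_path),
                        rows = nrow(mat), cols = ncol(mat)),
      samplesheet = list(path = basename(ss_path),
                         rows = nrow(ss), cols = ncol(ss)),
      truth = list(path = basename(truth_path),
                   edges_control = nrow(truth$true_edges_control),
                   edges_tumor = nrow(truth$true_edges_tumor))
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Example cohort configuration with the full planted scenario
#'
#' A ready-made [synthetic_config()] emulating the study conditions end to
#' end: 14 matched pairs, 300 miRNAs, strong planted correlation modules
#' (rho = 0.95) partially rewired between conditions, one clock-targeting
#' miRNA planted at log2 shift -2.766 (signed fold change about -6.8) that
#' loses all its control-network edges in tumor, a second equally shifted but
#' non-clock-targeting miRNA, and the TIMELESS mRNA negatively coupled
#' (rho = -0.32) to its targeting miRNA.
#'
#' @param seed Integer master seed.
#' @param noise_sd Noise level in log2 units (default 0.2).
#' @return A `synthetic_config`.
#' @export
example_cohort_config <- function(seed = 1L, noise_sd = 0.2) {
  sym <- function(i) sprintf("hsa-miR-s%03d", i)
  # planted candidate: member of a control module whose edges all vanish in tumor
  candidate <- sym(1)
  mods_control <- list(
    list(members = sym(1:5), rho = 0.95),     # candidate's module
    list(members = sym(6:10), rho = 0.95),
    list(members = sym(11:15), rho = 0.9),
    list(members = sym(16:20), rho = -0.85)
  )
  mods_tumor <- list(
    list(members = sym(2:5), rho = 0.95),     # candidate dropped: edges lost
    list(members = sym(6:10), rho = 0.95),    # preserved (common edges)
    list(members = sym(21:25), rho = 0.9),    # tumor-exclusive module
    list(members = sym(16:20), rho = 0.85)    # sign flip relative to control
  )
  de <- c(-2.766, -2.766, 1.2)
  names(de) <- c(candidate, sym(30), sym(31))
  synthetic_config(
    n_patients = 14, n_mirnas = 300, clock_gene_symbols = "TIMELESS",
    modules_control = mods_control, modules_tumor = mods_tumor,
    de_effects = de,
    coupling = list(list(mirna = candidate, gene = "TIMELESS", rho = -0.32)),
    noise_sd = noise_sd, seed = seed
  )
}

#' Target map matching the example cohort's planted scenario
#'
#' The planted candidate miRNA targets TIMELESS; two non-differential module
#' miRNAs target other clock genes so the annotation path is exercised.
#'
#' @return A `target_map`.
#' @export
example_target_map <- function() {
  target_map(list(
    "hsa-miR-s001" = "TIMELESS",
    "hsa-miR-s006" = c("PER1", "CLOCK"),
    "hsa-miR-s011" = "CRY1"
  ))
}
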