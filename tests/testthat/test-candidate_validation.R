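fake_de <- function(symbols, log2fc, dirs) {
  data.frame(symbol = symbols, mean_log2_diff = log2fc,
             signed_fc = signed_fold_change(log2fc),
             direction = factor(dirs, levels = c("up", "down", "ns")),
             stringsAsFactors = FALSE)
}

fake_partition <- function(common = NULL, ctl_excl = NULL, tum_excl = NULL) {
  mk <- function(p) {
    if (is.null(p)) {
      return(data.frame(symbol_a = character(), symbol_b = character(),
                        sign = character()))
    }
    data.frame(symbol_a = vapply(p, `[[`, "", 1),
               symbol_b = vapply(p, `[[`, "", 2),
               sign = "+", stringsAsFactors = FALSE)
  }
  structure(list(common = mk(common), sign_flip = mk(NULL),
                 tumor_exclusive = mk(tum_excl),
                 control_exclusive = mk(ctl_excl),
                 venn_counts = c(common = length(common), sign_flip = 0L,
                                 tumor_exclusive = length(tum_excl),
                                 control_exclusive = length(ctl_excl))),
            class = "edge_partition")
}

topo_of <- function(syms, dc) {
  data.frame(node = syms, degree_centrality = dc, stringsAsFactors = FALSE)
}

test_that("candidate ranking combines eligibility, rewiring and hub change", {
  de <- fake_de(c("m1", "m2", "m3"), c(-2.766, -2.766, 0.1),
                c("down", "down", "ns"))
  part <- fake_partition(
    common = list(c("m2", "x")),
    ctl_excl = list(c("m1", "a"), c("m1", "b"), c("m3", "c"))
  )
  targets <- target_map(list(m1 = "TIMELESS", m3 = "CRY1"))
  topo_c <- topo_of(c("m1", "m2", "m3"), c(0.4, 0.2, 0.1))
  topo_t <- topo_of(c("m1", "m2", "m3"), c(0.0, 0.2, 0.1))

  ranked <- rank_candidates(de, part, targets, topo_c, topo_t)
  # m2 is DE but not clock-targeting; m3 targets but is ns: only m1 eligible
  expect_equal(ranked$symbol, "m1")
  expect_equal(ranked$rank, 1L)
  expect_equal(ranked$lost_edge_fraction, 1)  # both control edges lost
  expect_equal(ranked$hub_delta, 0.4)
  expect_equal(ranked$score, 2.766 + 1 + 0.4)

  # no eligible symbols -> empty ranking
  none <- rank_candidates(de, part, target_map(list(m9 = "PER1")),
                          topo_c, topo_t)
  expect_equal(nrow(none), 0)

  # weight scaling preserves the ranking (scale equivariance)
  de2 <- fake_de(c("m1", "m3"), c(-2.766, -1.2), c("down", "down"))
  r1 <- rank_candidates(de2, part, targets, topo_c, topo_t,
                        weights = c(1, 1, 1))
  r2 <- rank_candidates(de2, part, targets, topo_c, topo_t,
                        weights = c(7, 7, 7))
  expect_equal(r1$symbol, r2$symbol)
  expect_equal(r2$score, 7 * r1$score)

  expect_error(rank_candidates(de, part, targets, topo_c, topo_t,
                               weights = c(1, 1)), "weights")
  expect_error(rank_candidates(de, part, targets, topo_c, topo_t,
                               weights = c(1, 1, -1)), "weights")
})

test_that("ties break by fold-change magnitude then symbol", {
  de <- fake_de(c("mB", "mA"), c(1.5, 1.5), c("up", "up"))
  part <- fake_partition()
  targets <- target_map(list(mA = "PER1", mB = "PER1"))
  topo <- topo_of(c("mA", "mB"), c(0, 0))
  ranked <- rank_candidates(de, part, targets, topo, topo)
  expect_equal(ranked$symbol, c("mA", "mB"))
})

test_that("gene-miRNA correlation detects planted inverse coupling", {
  expect_equal(gene_mirna_correlation(-(1:6), 1:6)$r, -1)

  # planted rho = -0.32 at n = 210: r concentrates near the target
  in_band <- 0L
  reps <- 40
  for (s in seq_len(reps)) {
    cfg <- synthetic_config(
      n_patients = 210, n_mirnas = 2, clock_gene_symbols = "TIMELESS",
      coupling = list(list(mirna = "hsa-miR-s001", gene = "TIMELESS",
                           rho = -0.32)),
      seed = 5000 + s
    )
    set <- generate_cohort(cfg)$set
    r <- gene_mirna_correlation(set$control["TIMELESS", ],
                                set$control["hsa-miR-s001", ])$r
    if (r >= -0.45 && r <= -0.19) in_band <- in_band + 1L
  }
  expect_gte(in_band / reps, 0.95 - 2 * sqrt(0.05 * 0.95 / reps))

  # independent vectors: |r| < 0.28 for n = 50 in most repeats
  set.seed(41)
  null_small <- mean(replicate(100, abs(cor(rnorm(50), rnorm(50))) < 0.28))
  expect_gte(null_small, 0.90)
})

test_that("ddct conventions are reciprocal and scale correctly", {
  expect_equal(ddct(5, 5, "paper"), 1.0)
  expect_equal(ddct(5, 5, "livak"), 1.0)
  expect_equal(ddct(8, 6, "paper"), 0.25)
  expect_equal(ddct(8, 6, "livak"), 4.0)
  for (cal in c(2, 7.5)) for (tgt in c(1, 6.25)) {
    expect_equal(ddct(cal, tgt, "paper"), 1 / ddct(cal, tgt, "livak"))
    expect_equal(ddct(cal, tgt + 1, "paper"), 2 * ddct(cal, tgt, "paper"))
  }
  # delta-Ct subtraction rule: target minus reference
  expect_equal(delta_ct(c(30, 32), c(20, 22)), 10)
  expect_error(delta_ct(c(30, 50), 20), "\\(0, 45\\)")
  expect_equal(ct_ratio(ct_target = 20, ct_reference = 25), 1.25)
})

test_that("median split and chi-squared match hand computation", {
  v <- c(1, 2, 3, 4, 5)
  out <- median_split_association(v, c("x", "x", "x", "y", "y"))
  expect_equal(unname(rowSums(out$table)), c(3, 2))  # low gets the tied median

  # [[10, 0], [0, 10]] by construction
  vals <- c(1:10, 11:20)
  phen <- rep(c("A", "B"), each = 10)
  res <- median_split_association(vals, phen)
  expect_equal(unname(res$chi2), 20.0)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, 7.744216431e-6, tolerance = 1e-8)

  # chi2 equals sum (O - E)^2 / E on the emitted table
  set.seed(42)
  v2 <- rnorm(40)
  p2 <- sample(c("a", "b", "c"), 40, replace = TRUE)
  r2 <- median_split_association(v2, p2)
  O <- r2$table
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(r2$chi2, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_equal(r2$df, (nrow(O) - 1) * (ncol(O) - 1))

  expect_error(median_split_association(v, rep("x", 5)), "categories")
  expect_error(median_split_association(1:3, c("a", "b", "a")), "at least 4")
  # calibration: p roughly uniform under independence
  set.seed(43)
  ps <- replicate(200, {
    median_split_association(rnorm(40),
                             sample(c("a", "b"), 40, TRUE))$p_value
  })
  expect_gt(mean(ps <= 0.5), 0.35)
  expect_lt(mean(ps <= 0.05), 0.12)
})

test_that("MSI calls follow the Bethesda anchors with interpolation flagged", {
  expect_equal(msi_classify(4)$call, "MSI-H")
  expect_equal(msi_classify(5)$call, "MSI-H")
  expect_equal(msi_classify(2)$call, "MSI-L")
  expect_equal(msi_classify(0)$call, "MSS")
  expect_false(msi_classify(2)$interpolated)
  expect_true(msi_classify(1)$interpolated)
  expect_equal(msi_classify(1)$call, "MSI-L")
  expect_equal(msi_classify(3)$call, "MSI-L")
  expect_error(msi_classify(6), "0..5")
  expect_error(msi_classify(-1), "0..5")
  expect_error(msi_classify(2.5), "0..5")
})
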