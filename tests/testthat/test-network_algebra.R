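net_from <- function(condition, pairs, signs, r_cut = 0.8, alpha = 0.05) {
  edges <- data.frame(
    symbol_a = vapply(pairs, `[[`, "", 1),
    symbol_b = vapply(pairs, `[[`, "", 2),
    r = ifelse(signs == "+", 0.9, -0.9),
    stringsAsFactors = FALSE
  )
  correlation_network(condition, edges, r_cut = r_cut, alpha = alpha)
}

pk <- function(df) paste(df$symbol_a, df$symbol_b, sep = "\r")

test_that("partition separates common, sign-flip and exclusive pairs", {
  control <- net_from("control",
                      list(c("a", "b"), c("b", "c"), c("c", "d")),
                      c("+", "+", "-"))
  tumor <- net_from("tumor",
                    list(c("a", "b"), c("b", "c"), c("d", "e")),
                    c("+", "-", "+"))
  part <- partition_networks(tumor, control)
  expect_equal(pk(part$common), "a\rb")
  expect_equal(pk(part$sign_flip), "b\rc")
  expect_equal(pk(part$control_exclusive), "c\rd")
  expect_equal(pk(part$tumor_exclusive), "d\re")
  expect_equal(unname(part$venn_counts), c(1L, 1L, 1L, 1L))
  expect_equal(part$sign_flip$sign_tumor, "-")
  expect_equal(part$sign_flip$sign_control, "+")
})

test_that("identical and disjoint networks are degenerate partitions", {
  a <- net_from("control", list(c("a", "b"), c("c", "d")), c("+", "-"))
  b <- net_from("tumor", list(c("a", "b"), c("c", "d")), c("+", "-"))
  part <- partition_networks(b, a)
  expect_equal(nrow(part$common), 2)
  expect_equal(nrow(part$sign_flip) + nrow(part$tumor_exclusive) +
                 nrow(part$control_exclusive), 0)

  d <- net_from("tumor", list(c("x", "y")), "+")
  part2 <- partition_networks(d, a)
  expect_equal(nrow(part2$common), 0)
  expect_equal(nrow(part2$sign_flip), 0)
  expect_equal(nrow(part2$tumor_exclusive), 1)
  expect_equal(nrow(part2$control_exclusive), 2)
})

test_that("threshold mismatch between networks is an error", {
  a <- net_from("control", list(c("a", "b")), "+", r_cut = 0.8)
  b <- net_from("tumor", list(c("a", "b")), "+", r_cut = 0.6)
  expect_error(partition_networks(b, a), "thresholds")
})

test_that("partition agrees with brute force and mirrors on random instances", {
  set.seed(20)
  syms <- sprintf("m%02d", 1:12)
  for (i in 1:60) {
    rand_edges <- function() {
      n <- sample(0:15, 1)
      if (n == 0) {
        return(data.frame(symbol_a = character(), symbol_b = character(),
                          r = numeric()))
      }
      pairs <- unique(t(replicate(n, sort(sample(syms, 2)))))
      data.frame(symbol_a = pairs[, 1], symbol_b = pairs[, 2],
                 r = round(runif(nrow(pairs), -1, 1), 3),
                 stringsAsFactors = FALSE)
    }
    te <- rand_edges()
    ce <- rand_edges()
    tn <- correlation_network("tumor", te)
    cn <- correlation_network("control", ce)
    part <- partition_networks(tn, cn)

    want <- partition_bruteforce(
      pk(tn$edges), tn$edges$sign, pk(cn$edges), cn$edges$sign
    )
    expect_identical(sort(pk(part$common)), want$common)
    expect_identical(sort(pk(part$sign_flip)), want$sign_flip)
    expect_identical(sort(pk(part$tumor_exclusive)), want$tumor_exclusive)
    expect_identical(sort(pk(part$control_exclusive)), want$control_exclusive)

    # disjointness and cover
    all_keys <- c(pk(part$common), pk(part$sign_flip),
                  pk(part$tumor_exclusive), pk(part$control_exclusive))
    expect_false(anyDuplicated(all_keys) > 0)
    expect_setequal(all_keys, union(pk(tn$edges), pk(cn$edges)))

    # mirror symmetry: swapping arguments swaps the exclusive sets
    cn2 <- correlation_network("tumor", ce)
    tn2 <- correlation_network("control", te)
    mirror <- partition_networks(cn2, tn2)
    expect_setequal(pk(mirror$common), pk(part$common))
    expect_setequal(pk(mirror$sign_flip), pk(part$sign_flip))
    expect_setequal(pk(mirror$tumor_exclusive), pk(part$control_exclusive))
    expect_setequal(pk(mirror$control_exclusive), pk(part$tumor_exclusive))
  }
})

alias_fixture <- function() {
  path <- tempfile(fileext = ".txt")
  writeLines(c(
    "MIMAT0000250\thsa-miR-139;hsa-miR-139-5p;",
    "MIMAT0004552\thsa-miR-139-3p;",
    "MIMAT0000731\thsa-miR-378;hsa-miR-378a-3p;",
    "MIMAT0022837\thsa-miR-378;hsa-miR-378a-5p;",
    "MIMAT0000062\thsa-let-7a;hsa-let-7a-5p;"
  ), path)
  path
}

test_that("symbol resolution returns the latest alias and keeps ambiguities", {
  al <- load_alias_table(alias_fixture())
  expect_equal(resolve_symbol("hsa-miR-139", al), "hsa-miR-139-5p")
  # legacy name matching two mature products stays unchanged
  expect_message(out <- resolve_symbol("miR-378", al), "unresolved")
  expect_equal(out, "miR-378")
  # fixed point and idempotence
  expect_equal(resolve_symbol("hsa-miR-139-5p", al), "hsa-miR-139-5p")
  once <- suppressMessages(
    resolve_symbols(c("hsa-miR-139", "miR-378", "LET-7A"), al))
  twice <- suppressMessages(resolve_symbols(as.character(once), al))
  expect_equal(as.character(once), as.character(twice))
  # case-insensitive, hsa- prefix normalized
  expect_equal(resolve_symbol("MIR-139", al), "hsa-miR-139-5p")
  expect_equal(resolve_symbol("LET-7A", al), "hsa-let-7a-5p")
  # unknown symbol kept as-is
  expect_message(keep <- resolve_symbol("miR-9999", al), "unresolved")
  expect_equal(keep, "miR-9999")
})

test_that("clock-controller tagging follows the at-least-one-member rule", {
  tm <- target_map(list(m1 = c("PER1", "CLOCK")))
  net <- net_from("tumor", list(c("m1", "m2"), c("m2", "m3")), c("+", "+"))
  tagged <- tag_clock_controllers(net, tm)
  expect_equal(tagged$edges$clock_controller, c(TRUE, FALSE))
  na <- tagged$node_attrs
  expect_true(na$clock_target[na$symbol == "m1"])
  expect_false(any(na$clock_target[na$symbol != "m1"]))

  # a validated-target table row: let-7e-5p targets PER1 and CLOCK
  t2 <- target_map(list(
    "hsa-let-7e-5p" = c("PER1", "CLOCK"),
    "hsa-miR-139-5p" = "TIMELESS"
  ))
  expect_setequal(t2[["hsa-let-7e-5p"]], c("PER1", "CLOCK"))
  net2 <- net_from("control",
                   list(c("hsa-let-7e-5p", "hsa-miR-139-5p")), "+")
  tag2 <- tag_clock_controllers(net2, t2)
  expect_true(all(tag2$node_attrs$clock_target))

  # genes outside the clock universe are rejected; empty sets dropped
  expect_error(target_map(list(m1 = "MYC")), "outside the clock universe")
  expect_false("m2" %in% names(target_map(list(m1 = "PER1", m2 = character()))))
})

test_that("bundled annotation files load and behave as documented", {
  tm <- load_target_map(system.file("extdata", "clock_targets_validated.tsv",
                                    package = "clocknet"))
  expect_setequal(tm[["hsa-let-7e-5p"]], c("PER1", "CLOCK"))
  expect_equal(tm[["hsa-miR-139-5p"]], "TIMELESS")

  al <- load_alias_table(system.file("extdata", "mirna_aliases_synthetic.txt",
                                     package = "clocknet"))
  expect_equal(resolve_symbol("miR-139", al), "hsa-miR-139-5p")
  expect_equal(resolve_symbol("miR-125b", al), "hsa-miR-125b-5p")
  # the two legacy names shared by both mature products stay unchanged
  expect_message(expect_equal(resolve_symbol("miR-378", al), "miR-378"))
  expect_message(expect_equal(resolve_symbol("miR-34b", al), "miR-34b"))
})

test_that("partition tagging covers all four edge sets", {
  control <- net_from("control", list(c("a", "b"), c("c", "d")), c("+", "-"))
  tumor <- net_from("tumor", list(c("a", "b"), c("d", "e")), c("-", "+"))
  part <- partition_networks(tumor, control)
  tm <- target_map(list(a = "TIMELESS", d = "PER2"))
  tagged <- tag_clock_controllers(part, tm)
  expect_true(tagged$sign_flip$clock_controller)       # (a,b): a targets
  expect_true(tagged$control_exclusive$clock_controller)  # (c,d): d targets
  expect_true(tagged$tumor_exclusive$clock_controller)    # (d,e)
})
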