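# Rule loading, tier/taxon/Pfam filtering, transition indexing, and the
# database-coverage statistic.

ten_rule_table <- function() {
  tab <- do.call(rbind, lapply(1:10, function(i) {
    hydrox_rule_table(rule_id = sprintf("r%02d", i),
                      pfam = sprintf("PF%05d", i),
                      tier = c("strict", "medium", "loose")[
                        (i - 1) %% 3 + 1],
                      substrate_mass = 100 + i)
  }))
  tab$taxon <- rep(c("Viridiplantae", "Bacteria"), 5)
  tab
}

test_that("tier filtering keeps the requested nested subset", {
  tab <- ten_rule_table()
  strict <- rules_from_table(tab, tier = "strict")
  medium <- rules_from_table(tab, tier = "medium")
  loose <- rules_from_table(tab, tier = "loose")
  expect_length(strict, sum(tab$tier == "strict"))
  expect_length(loose, 10)
  expect_true(all(names(strict) %in% names(medium)))
  expect_true(all(names(medium) %in% names(loose)))
})

test_that("taxonomy filtering works at the association level", {
  tab <- ten_rule_table()
  vir <- rules_from_table(tab, tier = "loose", taxa = "Viridiplantae")
  expect_length(vir, 5)
  expect_true(all(vapply(vir, function(r)
    all(r$associations$taxon == "Viridiplantae"), logical(1))))
})

test_that("mass transitions are recomputed and checked on load", {
  tab <- hydrox_rule_table(substrate_mass = 100)
  tab$product_mass <- 115.9949
  rules <- rules_from_table(tab)
  expect_equal(rules[[1]]$mass_transition, 15.9949, tolerance = 1e-9)
  tab$mass_transition <- 20  # inconsistent with the masses
  expect_error(rules_from_table(tab), "inconsistent")
})

test_that("stereo, multi-substrate, and broken SMARTS rules are filtered", {
  stereo <- hydrox_rule_table(rule_id = "stereo")
  stereo$smarts <- "[C@H:1](O)>>[C:1](O)O"
  expect_length(rules_from_table(stereo), 0)
  slash <- hydrox_rule_table(rule_id = "cis")
  slash$smarts <- "[CH2:1]/[CH2:2]>>[CH1:1]=[CH1:2]"
  expect_length(rules_from_table(slash), 0)
  multi <- hydrox_rule_table(rule_id = "multi")
  multi$smarts <- "[CH3:1].[OH2:2]>>[CH2:1][OH:2]"
  expect_length(rules_from_table(multi), 0)
  broken <- hydrox_rule_table(rule_id = "broken")
  broken$smarts <- "[CH3:1>>[CH2:1]O"
  expect_warning(out <- rules_from_table(broken), "broken")
  expect_length(out, 0)
})

test_that("a bidirectional rule is indexed under both signed transitions", {
  rules <- rules_from_table(hydrox_rule_table())
  idx <- build_transition_index(rules)
  expect_identical(nrow(idx$table), 2L)
  expect_equal(sort(idx$table$transition), c(-15.994915, 15.994915))
  hit <- transition_lookup(idx, 15.9950, 0.002)
  expect_identical(hit$rule_id, "hydrox")
  expect_identical(nrow(transition_lookup(idx, 7, 0.002)), 0L)
  empty <- build_transition_index(list())
  expect_identical(nrow(empty$table), 0L)
})

test_that("index lookups equal a linear scan over many random rules", {
  withr::local_seed(21)
  n <- 400
  tab <- do.call(rbind, lapply(seq_len(n), function(i) {
    hydrox_rule_table(rule_id = sprintf("r%03d", i),
                      direction = sample(c("both", "forward"), 1),
                      substrate_mass = 100)
  }))
  tab$product_mass <- tab$substrate_mass + runif(n, -60, 60)
  rules <- rules_from_table(tab)
  idx <- build_transition_index(rules)
  for (delta in c(runif(25, -60, 60), 15.994915)) {
    tol <- runif(1, 0.001, 0.5)
    got <- sort(unique(transition_lookup(idx, delta, tol)$rule_id))
    expect_identical(got, linear_scan_lookup(rules, delta, tol))
  }
})

test_that("promiscuous Pfam associations are dropped, then rules pruned", {
  tab <- do.call(rbind, lapply(1:7, function(i)
    hydrox_rule_table(rule_id = sprintf("r%d", i), pfam = "PF_GENERIC")))
  tab2 <- hydrox_rule_table(rule_id = "r8", pfam = "PF_SPEC")
  rules <- rules_from_table(rbind(tab, tab2), tier = "strict")
  kept <- pfam_filter(rules, max_reactions_per_pfam = 6)
  expect_identical(names(kept), "r8")          # 7-rule Pfam dropped
  kept_all <- pfam_filter(rules, max_reactions_per_pfam = Inf)
  expect_identical(names(kept_all), names(rules))
  expect_identical(names(pfam_filter(kept, 6)), names(kept))  # idempotent
})

test_that("coverage chi-square matches the equal-probability null", {
  r1 <- coverage_chisq(134, 187)
  expect_equal(r1$chi2, 35.09, tolerance = 0.01)
  expect_lt(r1$p, 0.001)
  r2 <- coverage_chisq(132, 374)
  expect_equal(r2$chi2, 32.353, tolerance = 0.001)
  expect_lt(r2$p, 0.001)
  null <- coverage_chisq(50, 100)
  expect_equal(null$chi2, 0)
  expect_equal(null$p, 1)
  # symmetry of found vs missing
  expect_equal(coverage_chisq(53, 187)$chi2, r1$chi2)
  # oracle: base R's goodness-of-fit test
  oracle <- suppressWarnings(chisq.test(c(134, 53), p = c(0.5, 0.5)))
  expect_equal(r1$chi2, unname(oracle$statistic))
  expect_equal(r1$p, oracle$p.value)
  expect_error(coverage_chisq(10, 0), "positive")
  expect_error(coverage_chisq(11, 10), "found")
})
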