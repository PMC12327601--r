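# Reaction centers, likelihood extraction, and score-set comparison.

test_that("reaction likelihood is the maximum score over the center", {
  expect_equal(reaction_likelihood(c(`3` = 0.2, `5` = 0.7), c(3L, 5L)), 0.7)
  expect_equal(reaction_likelihood(c(`0` = 0, `1` = 0), c(0L, 1L)), 0)
  expect_error(reaction_likelihood(c(`0` = 0.5), c(0L, 2L)), "atom.*2")
  # worked example: a 0.94 site-of-metabolism score at the modified carbon
  scores <- rep(0.1, 20)
  scores[7] <- 0.94
  names(scores) <- as.character(0:19)
  expect_equal(reaction_likelihood(scores, c(6L, 7L)), 0.94)
  # monotone: raising any center score never lowers the likelihood
  withr::local_seed(31)
  for (i in 1:20) {
    sc <- setNames(runif(10), as.character(0:9))
    center <- sample(0:9, 3)
    base <- reaction_likelihood(sc, center)
    bump <- sc
    j <- as.character(sample(center, 1))
    bump[j] <- min(1, bump[j] + runif(1))
    expect_gte(reaction_likelihood(bump, center), base)
  }
})

test_that("atom-score tables read and validate", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("structure_id,atom_index,score",
               "mol1,0,0.2", "mol1,1,0.9", "mol2,0,0.4"), path)
  sc <- read_atom_scores(path)
  expect_named(sc, c("mol1", "mol2"))
  expect_equal(sc$mol1[["1"]], 0.9)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("structure_id,atom_index,score", "m,0,1.2"), bad)
  expect_error(read_atom_scores(bad), "0, 1")
})

test_that("small-sample Mann-Whitney matches full enumeration", {
  res <- compare_score_sets(c(0.9, 0.8), c(0.2, 0.1))
  expect_equal(res$U, 4)  # complete separation: U = n1 * n2
  expect_true(res$exact)
  oracle <- brute_force_mw(c(0.9, 0.8), c(0.2, 0.1))
  expect_equal(res$p, oracle$p)
  # identical samples: U at its null center
  same <- compare_score_sets(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$U, 9 / 2)
  expect_equal(same$p, 1)
})

test_that("exact p agrees with brute force across random tied inputs", {
  withr::local_seed(17)
  for (trial in 1:15) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    # draw from a small grid so ties are frequent
    x <- sample(seq(0, 1, by = 0.25), n1, replace = TRUE)
    y <- sample(seq(0, 1, by = 0.25), n2, replace = TRUE)
    got <- compare_score_sets(x, y)
    oracle <- brute_force_mw(x, y)
    expect_true(got$exact)
    expect_equal(got$U, oracle$U)
    expect_equal(got$p, oracle$p, tolerance = 1e-12)
  }
})

test_that("exact p matches the closed-form null when there are no ties", {
  withr::local_seed(23)
  for (trial in 1:10) {
    n1 <- sample(4:12, 1)
    n2 <- sample(4:12, 1)
    x <- rnorm(n1)
    y <- rnorm(n2, 0.5)
    got <- compare_score_sets(x, y)
    oracle <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(got$U, unname(oracle$statistic))
    expect_equal(got$p, oracle$p.value, tolerance = 1e-10)
  }
})

test_that("U statistics of the two orderings sum to n1 * n2", {
  withr::local_seed(29)
  for (trial in 1:10) {
    x <- runif(sample(3:15, 1))
    y <- runif(sample(3:15, 1))
    expect_equal(compare_score_sets(x, y)$U + compare_score_sets(y, x)$U,
                 length(x) * length(y))
  }
  expect_error(compare_score_sets(numeric(0), 1), "empty")
})

test_that("large samples fall back to the tie-corrected normal", {
  withr::local_seed(37)
  x <- rnorm(30, 1)
  y <- rnorm(30)
  got <- compare_score_sets(x, y)  # n1*n2 = 900 > 400
  expect_false(got$exact)
  oracle <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$p, oracle$p.value, tolerance = 1e-10)
})

test_that("generated score sets separate; null sets do not", {
  ss <- generate_score_sets(n = 50, seed = 4)
  expect_lt(compare_score_sets(ss$known, ss$random)$p, 0.05)
  expect_gt(median(ss$known), median(ss$random))
  expect_identical(generate_score_sets(n = 50, seed = 4), ss)
  # same-distribution draws give unremarkable p across seeds
  withr::local_seed(41)
  ps <- vapply(1:40, function(i) {
    compare_score_sets(rbeta(10, 2, 2), rbeta(10, 2, 2))$p
  }, numeric(1))
  expect_gt(median(ps), 0.1)
})

test_that("reaction centers localize the transformed atoms", {
  expect_true(chem_backend_available())
  arom <- rules_from_table(local({
    t <- hydrox_rule_table(rule_id = "arom_oh")
    t$smarts <- "[cH:1]>>[c:1]O"
    t$substrate_mass <- 78.04695
    t$product_mass <- 94.041865
    t
  }))[[1]]
  center <- reaction_center("c1ccccc1", "Oc1ccccc1", arom)
  expect_length(center, 1)
  expect_identical(attr(center, "method"), "template")
  desat <- rules_from_table(local({
    t <- hydrox_rule_table(rule_id = "desat")
    t$smarts <- "[CH2:1][CH2:2]>>[CH1:1]=[CH1:2]"
    t$substrate_mass <- 58.078250
    t$product_mass <- 56.062600
    t
  }))[[1]]
  center2 <- reaction_center("CCCC", "CC=CC", desat)
  expect_length(center2, 2)
  expect_error(reaction_center("CCO", "CCO", NULL), "empty center")
  # MCS fallback without a template still finds the hydroxylated atom
  center3 <- reaction_center("c1ccccc1", "Oc1ccccc1", NULL)
  expect_identical(attr(center3, "method"), "mcs")
  expect_gte(length(center3), 1)
})

test_that("heuristic atom scores are bounded and indexed from zero", {
  expect_true(chem_backend_available())
  sc <- heuristic_atom_scores(c("CCO", "c1ccccc1"))
  expect_named(sc$CCO, as.character(0:2))
  expect_true(all(sc$CCO >= 0 & sc$CCO <= 1))
  uni <- heuristic_atom_scores("CCO", method = "uniform")
  expect_true(all(uni$CCO == 0.5))
})
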