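# MAD rescaling, Pearson correlation with p-values, mutual ranks, and
# decay-weighted networks.

test_that("raw median absolute deviation matches hand evaluation", {
  expect_equal(median_abs_dev(c(1, 2, 3, 4, 100)), 1)
  expect_equal(median_abs_dev(c(5, 5, 5)), 0)
  expect_equal(median_abs_dev(c(-1, 1)), 1)
  expect_error(median_abs_dev(numeric(0)), "empty")
})

test_that("MAD rescaling centers rows and drops constant rows", {
  m <- rbind(r1 = c(1, 2, 3, 4, 100), r2 = c(7, 7, 7, 7, 7))
  colnames(m) <- paste0("s", 1:5)
  em <- expression_matrix(m)
  expect_message(out <- mad_rescale(em), "dropped 1")
  expect_identical(rownames(out$values), "r1")
  expect_equal(unname(out$values[1, ]), c(-2, -1, 0, 1, 97))
  # normalization identity on arbitrary rows
  withr::local_seed(42)
  m2 <- matrix(rnorm(50), 5, 10,
               dimnames = list(paste0("t", 1:5), paste0("s", 1:10)))
  r2 <- mad_rescale(expression_matrix(m2))
  expect_equal(apply(r2$values, 1, median), rep(0, 5),
               ignore_attr = TRUE)
  expect_equal(apply(r2$values, 1, median_abs_dev), rep(1, 5),
               ignore_attr = TRUE)
  m3 <- matrix(1, 2, 5, dimnames = list(c("a", "b"), paste0("s", 1:5)))
  expect_error(suppressMessages(mad_rescale(expression_matrix(m3))),
               "no variable rows")
})

test_that("correlation p-values follow the t formula", {
  x <- c(1, 2, 3, 4, 5, 6)
  em <- expression_matrix(matrix(x, 1, 6,
                                 dimnames = list("T1", paste0("s", 1:6))))
  ft <- feature_table("F1", 100,
                      matrix(2 * x, 1, 6,
                             dimnames = list(NULL, paste0("s", 1:6))))
  ed <- correlate_pairs(em, ft)
  expect_equal(ed$r, 1)
  expect_equal(ed$p, 0)

  # centered orthogonal pair falls below the |r| threshold
  em2 <- expression_matrix(matrix(c(1, 2, 3, 4), 1, 4,
                                  dimnames = list("T1", paste0("s", 1:4))))
  ft2 <- feature_table("F1", 100,
                       matrix(c(2, 0, 0, 2), 1, 4,
                              dimnames = list(NULL, paste0("s", 1:4))))
  expect_identical(nrow(correlate_pairs(em2, ft2, min_abs_r = 0.1)), 0L)

  # general case agrees with the standard test of zero correlation
  withr::local_seed(7)
  n <- 48
  a <- rnorm(n)
  b <- 0.7 * a + rnorm(n, sd = 0.6)
  em3 <- expression_matrix(matrix(a, 1, n,
                                  dimnames = list("T1",
                                                  sprintf("s%02d", 1:n))))
  ft3 <- feature_table("F1", 100,
                       matrix(abs(b) + 1, 1, n,
                              dimnames = list(NULL, sprintf("s%02d", 1:n))))
  ed3 <- correlate_pairs(em3, ft3, min_abs_r = 0.1)
  oracle <- cor.test(a, abs(b) + 1)
  expect_equal(ed3$r, unname(oracle$estimate))
  expect_equal(ed3$p, oracle$p.value, tolerance = 1e-12)
  # a strong correlation at this sample size lands far below any
  # conventional threshold (r = 0.744 at n = 48 gives p ~ 1e-9)
  t744 <- 0.744 * sqrt((48 - 2) / (1 - 0.744^2))
  expect_lt(2 * pt(-t744, 46), 1e-8)
})

test_that("mutual ranks are geometric means of directed ranks", {
  ed <- data.frame(
    transcript_id = c("t1", "t1", "t2", "t2"),
    feature_id = c("f1", "f2", "f1", "f2"),
    r = c(0.9, 0.5, 0.4, 0.8), p = 0.01, stringsAsFactors = FALSE)
  mr <- mutual_rank(ed)
  # mutual top partners score exactly 1
  expect_equal(mr$mr[mr$transcript_id == "t1" & mr$feature_id == "f1"], 1)
  expect_equal(mr$mr[mr$transcript_id == "t2" & mr$feature_id == "f2"], 1)
  # both directed ranks 2 -> geometric mean 2
  expect_equal(mr$mr[mr$transcript_id == "t1" & mr$feature_id == "f2"], 2)
  # shuffling edge order leaves mutual ranks untouched
  withr::local_seed(3)
  perm <- sample(nrow(ed))
  mr2 <- mutual_rank(ed[perm, ])
  key <- paste(mr$transcript_id, mr$feature_id)
  key2 <- paste(mr2$transcript_id, mr2$feature_id)
  expect_equal(mr2$mr[match(key, key2)], mr$mr)
})

test_that("directed rank products reproduce a brute-force oracle", {
  withr::local_seed(11)
  tx <- sprintf("t%02d", 1:12)
  fx <- sprintf("f%02d", 1:9)
  ed <- expand.grid(transcript_id = tx, feature_id = fx,
                    stringsAsFactors = FALSE)
  ed$r <- runif(nrow(ed), -1, 1)
  ed$p <- 0.05
  mr <- mutual_rank(ed)
  for (k in sample(nrow(mr), 20)) {
    t_edges <- ed[ed$transcript_id == mr$transcript_id[k], ]
    f_edges <- ed[ed$feature_id == mr$feature_id[k], ]
    rt <- rank(-abs(t_edges$r))[t_edges$feature_id == mr$feature_id[k]]
    rf <- rank(-abs(f_edges$r))[f_edges$transcript_id ==
                                  mr$transcript_id[k]]
    expect_equal(mr$mr[k], sqrt(rt * rf))
  }
})

test_that("decay weights follow the closed form and the cutoff", {
  expect_equal(decay_weight(1, 5), 1)
  expect_equal(decay_weight(1, 50), 1)
  expect_equal(decay_weight(11, 10), exp(-1))
  ed <- data.frame(transcript_id = c("t1", "t2", "t3"),
                   feature_id = c("f1", "f2", "f3"),
                   r = 0.9, p = 0.01, mr = c(1, 47.05, 48),
                   stringsAsFactors = FALSE)
  nets <- decay_weights(ed, decay_rates = 10)
  net <- nets[["10"]]
  expect_true(all(c("t1", "t2") %in% net$transcript_id))
  expect_false("t3" %in% net$transcript_id)  # weight < 0.01 excluded
  expect_equal(net$weight[net$transcript_id == "t2"],
               exp(-(47.05 - 1) / 10), tolerance = 1e-12)
  expect_error(decay_weights(ed, decay_rates = -1), "positive")
})

test_that("weights are bounded, monotone, and networks nest by decay rate", {
  withr::local_seed(5)
  mrs <- c(1, sort(runif(60, 1, 120)))
  for (dr in c(5, 10, 25, 50)) {
    w <- decay_weight(mrs, dr)
    expect_true(all(w > 0 & w <= 1))
    expect_true(all(diff(w) <= 0))          # non-increasing in mr
    expect_equal(w[1], 1)                   # w = 1 iff mr = 1
    expect_true(all(w[-1] < 1))
  }
  for (mr in c(2, 11, 80)) {
    expect_true(all(diff(decay_weight(mr, c(5, 10, 25, 50))) > 0))
  }
  ed <- data.frame(transcript_id = sprintf("t%02d", seq_along(mrs)),
                   feature_id = sprintf("f%02d", seq_along(mrs)),
                   r = 0.5, p = 0.01, mr = mrs, stringsAsFactors = FALSE)
  nets <- decay_weights(ed)
  sizes <- vapply(nets, nrow, integer(1))
  expect_true(all(diff(sizes) >= 0))
  for (i in 1:3) {
    smaller <- paste(nets[[i]]$transcript_id, nets[[i]]$feature_id)
    larger <- paste(nets[[i + 1]]$transcript_id, nets[[i + 1]]$feature_id)
    expect_true(all(smaller %in% larger))
  }
})

test_that("planted transcript-feature pairs outcorrelate decoys", {
  run <- toy_run()
  ed <- run$res$correlations
  truth <- run$toy$truth
  planted <- ed$transcript_id %in% truth$transcripts &
    ed$feature_id %in% truth$feature_ids
  decoy <- startsWith(ed$transcript_id, "TX_dec") &
    startsWith(ed$feature_id, "FT_dec")
  expect_gt(mean(abs(ed$r[planted])), mean(abs(ed$r[decoy])))
})
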