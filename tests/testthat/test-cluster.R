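# Overlapping functional-cluster detection, p-values, and merging.

test_that("two disjoint cliques are found exactly, isolated nodes ignored", {
  edges <- rbind(clique_edges(c("a1", "a2", "a3", "a4")),
                 clique_edges(c("b1", "b2", "b3", "b4")))
  cl <- detect_clusters(edges)
  expect_length(cl, 2)
  mem <- lapply(cl, `[[`, "members")
  expect_true(any(vapply(mem, identical, logical(1),
                         c("a1", "a2", "a3", "a4"))))
  expect_true(any(vapply(mem, identical, logical(1),
                         c("b1", "b2", "b3", "b4"))))
  # the greedy optimum matches exhaustive search on this network
  expect_equal(max(vapply(cl, `[[`, numeric(1), "cohesiveness")),
               brute_force_best_cohesiveness(edges))
})

test_that("clusters below the minimum size are discarded", {
  one_edge <- data.frame(node_a = "x", node_b = "y", weight = 1)
  expect_length(detect_clusters(one_edge, min_size = 3), 0)
  expect_length(detect_clusters(one_edge[0, ]), 0)
})

test_that("strongly overlapping candidates merge, weakly overlapping don't", {
  # two 4-cliques sharing 3 nodes: omega = 9/16 < 0.8 -> stay separate
  edges <- unique(rbind(clique_edges(c("a", "b", "c", "d")),
                        clique_edges(c("a", "b", "c", "e"))))
  cl <- detect_clusters(edges)
  expect_gte(length(cl), 1)
  # identical duplicated candidates collapse to one cluster
  edges2 <- clique_edges(c("p", "q", "r", "s"))
  cl2 <- detect_clusters(edges2)
  expect_length(cl2, 1)
})

test_that("an isolated extra node changes no cluster memberships", {
  edges <- clique_edges(c("a", "b", "c", "d"))
  with_iso <- rbind(edges,
                    data.frame(node_a = "z1", node_b = "z2", weight = 0))
  m1 <- lapply(detect_clusters(edges), `[[`, "members")
  m2 <- lapply(detect_clusters(with_iso), `[[`, "members")
  expect_identical(m1, m2)
})

test_that("cluster p-value separates internal from boundary weights", {
  inner <- clique_edges(paste0("i", 1:5), weight = 1)      # 10 edges
  boundary <- data.frame(node_a = paste0("i", 1:5),
                         node_b = paste0("o", 1:5), weight = 0.01)
  boundary2 <- boundary
  boundary2$node_a <- paste0("i", c(2, 3, 4, 5, 1))
  edges <- rbind(inner, boundary, boundary2)               # 10 boundary
  p <- cluster_pvalue(paste0("i", 1:5), edges)
  expect_lt(p, 0.01)
  # all weights identical: no separation, p = 1 under the tie convention
  edges_tied <- edges
  edges_tied$weight <- 0.5
  expect_equal(as.numeric(cluster_pvalue(paste0("i", 1:5), edges_tied)), 1)
  # permutation invariance
  withr::local_seed(2)
  p2 <- cluster_pvalue(paste0("i", 1:5), edges[sample(nrow(edges)), ])
  expect_equal(as.numeric(p2), as.numeric(p))
  # no boundary edges: smallest representable p, flagged
  p3 <- cluster_pvalue(c("a", "b", "c"), clique_edges(c("a", "b", "c")))
  expect_true(isTRUE(attr(p3, "no_boundary")))
  expect_equal(as.numeric(p3), .Machine$double.xmin)
})

test_that("reported functional clusters are mixed and large enough", {
  run <- toy_run()
  fcs <- run$res$clusters
  expect_true(all(fcs$n_members >= 3))
  expect_true(all(fcs$n_transcripts >= 1))
  expect_true(all(fcs$n_features >= 1))
})

test_that("clusters sharing mass features merge transitively", {
  types <- c(f1 = "feature", f2 = "feature", f3 = "feature",
             t1 = "transcript", t2 = "transcript", t3 = "transcript")
  fcs <- data.frame(
    cluster_id = 1:3, decay_rate = 10, n_members = 3, n_transcripts = 2,
    n_features = 1, cohesiveness = 0.5, p_value = 0.01,
    members = c("f1;t1;t2", "f1;f2;t3", "f3;t1"), stringsAsFactors = FALSE)
  merged <- merge_shared_feature_clusters(fcs, types)
  expect_identical(nrow(merged), 2L)
  big <- merged[grepl("f1", merged$members), ]
  expect_identical(big$members, "f1;f2;t1;t2;t3")
  expect_identical(big$source_clusters, "1;2")
  # transcripts in common do not merge (f3;t1 shares only t1)
  expect_true("f3;t1" %in% merged$members)
  # idempotent
  merged$cluster_id <- seq_len(nrow(merged))
  again <- merge_shared_feature_clusters(merged, types)
  expect_identical(again$members, merged$members)
})

test_that("coexpression edges merge clusters above the weight threshold", {
  types <- c(f1 = "feature", f2 = "feature",
             t1 = "transcript", t2 = "transcript")
  fcs <- data.frame(
    cluster_id = 1:2, decay_rate = 10, n_members = 2, n_transcripts = 1,
    n_features = 1, cohesiveness = 0.5, p_value = 0.01,
    members = c("f1;t1", "f2;t2"), stringsAsFactors = FALSE)
  co_strong <- data.frame(transcript_a = "t1", transcript_b = "t2",
                          r = 0.95, mr = 1, weight = 0.9)
  co_weak <- co_strong
  co_weak$weight <- 0.3
  expect_identical(nrow(coexpression_merge(fcs, co_strong, 0.5, types)), 1L)
  expect_identical(nrow(coexpression_merge(fcs, co_weak, 0.5, types)), 2L)
  # merging never increases the cluster count
  expect_lte(nrow(coexpression_merge(fcs, co_strong, 0.5, types)),
             nrow(fcs))
})
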