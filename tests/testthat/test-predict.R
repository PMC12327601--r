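# Mass-pair matching, ghost insertion, enzyme support, DAG reduction and
# longest-path extraction.

two_node_setup <- function(masses, ids = paste0("N", seq_along(masses))) {
  data.frame(node_id = ids, kind = "measured", mass = masses,
             source_feature = ids, structures = "", stringsAsFactors = FALSE)
}

hydrox_index <- function() {
  build_transition_index(rules_from_table(hydrox_rule_table()))
}

test_that("mass pairs match indexed transitions in both orientations", {
  nodes <- two_node_setup(c(180.0634, 196.0583))
  pairs <- match_mass_pairs(nodes, hydrox_index(), tolerance = 0.002)
  expect_identical(nrow(pairs), 2L)  # forward and reverse of one rule
  fwd <- pairs[pairs$orientation == "forward", ]
  expect_identical(fwd$substrate_node, "N1")
  expect_identical(fwd$product_node, "N2")
  rev <- pairs[pairs$orientation == "reverse", ]
  expect_identical(rev$substrate_node, "N2")
  expect_identical(rev$product_node, "N1")
  # a 7 Da gap matches nothing
  none <- match_mass_pairs(two_node_setup(c(100, 107)), hydrox_index(),
                           tolerance = 0.002)
  expect_identical(nrow(none), 0L)
  # an exactly representable difference matches even at zero tolerance
  int_rule <- hydrox_rule_table(rule_id = "plus16", substrate_mass = 100)
  int_rule$product_mass <- 116
  int_idx <- build_transition_index(rules_from_table(int_rule))
  exact <- match_mass_pairs(two_node_setup(c(100, 116)), int_idx,
                            tolerance = 0)
  expect_identical(nrow(exact), 2L)
})

test_that("ghost nodes bridge two-step mass gaps", {
  nodes <- two_node_setup(c(180.0634, 212.0532))
  idx <- hydrox_index()
  pairs <- match_mass_pairs(nodes, idx, tolerance = 0.002)
  expect_identical(nrow(pairs), 0L)  # two hydroxylations apart
  gh <- insert_ghosts(pairs, nodes, idx, mode = "always",
                      tolerance = 0.002)
  ghosts <- gh$nodes[gh$nodes$kind == "ghost", ]
  expect_gte(nrow(ghosts), 1)
  expect_equal(ghosts$mass[1], 196.0583, tolerance = 0.002)
  # every ghost sits exactly one transition from its anchor
  for (k in seq_len(nrow(gh$pairs))) {
    sub <- gh$nodes[gh$nodes$node_id == gh$pairs$substrate_node[k], ]
    prod <- gh$nodes[gh$nodes$node_id == gh$pairs$product_node[k], ]
    expect_lte(abs(prod$mass - sub$mass - gh$pairs$transition[k]), 0.002)
  }
  off <- insert_ghosts(pairs, nodes, idx, mode = "off", tolerance = 0.002)
  expect_identical(off$pairs, pairs)
  expect_identical(off$nodes, nodes)
})

test_that("auto ghost mode only bridges unassigned features", {
  idx <- hydrox_index()
  # N1-N2 singly linked; N3 two steps from N2, unassigned
  nodes <- two_node_setup(c(180.0634, 196.058315, 228.048145))
  pairs <- match_mass_pairs(nodes, idx, tolerance = 0.002)
  expect_true(all(c("N1", "N2") %in%
                    c(pairs$substrate_node, pairs$product_node)))
  gh <- insert_ghosts(pairs, nodes, idx, mode = "auto", tolerance = 0.002)
  expect_gt(nrow(gh$pairs), nrow(pairs))
  expect_true("N3" %in% c(gh$pairs$substrate_node, gh$pairs$product_node))
})

test_that("enzyme support gates candidate pairs on Pfam and correlation", {
  desat <- data.frame(
    rule_id = "desat", reaction_ids = "RXN9",
    smarts = "[CH2:1][CH2:2]>>[CH1:1]=[CH1:2]", diameter = 2L,
    direction = "both", substrate_mass = 294.2195,
    product_mass = 292.2038, pfam_id = "PF00487",
    ec_number = "1.14.19.1", tier = "strict", taxon = "Viridiplantae",
    mass_transition = NA_real_, stringsAsFactors = FALSE)
  desat$mass_transition <- NULL
  rules <- rules_from_table(desat)
  idx <- build_transition_index(rules)
  nodes <- data.frame(node_id = c("crep@[M+H]+", "dehyd@[M+H]+"),
                      kind = "measured", mass = c(294.2195, 292.2038),
                      source_feature = c("crep", "dehyd"),
                      structures = "", stringsAsFactors = FALSE)
  pairs <- match_mass_pairs(nodes, idx, tolerance = 0.002)
  net <- data.frame(transcript_id = c("desaturase_tx", "unrelated_tx"),
                    feature_id = c("dehyd", "crep"), r = c(0.744, 0.9),
                    p = 1e-10, mr = 1, weight = c(0.9, 0.4),
                    stringsAsFactors = FALSE)
  ann <- data.frame(transcript_id = c("desaturase_tx", "unrelated_tx"),
                    pfam_ids = c("PF00487", "PF99999"),
                    category = c("tailoring", "other"),
                    stringsAsFactors = FALSE)
  out <- attach_enzyme_support(pairs, nodes, net, ann, rules,
                               cluster_restricted = FALSE)
  expect_gt(nrow(out), 0)
  expect_true(all(grepl("desaturase_tx", out$enzyme_support)))
  expect_false(any(grepl("unrelated_tx", out$enzyme_support)))
  # a transcript with only an unrelated Pfam cannot support alone
  ann2 <- ann
  ann2$pfam_ids <- c("PF99999", "PF99998")
  out2 <- attach_enzyme_support(pairs, nodes, net, ann2, rules,
                                cluster_restricted = FALSE)
  expect_identical(nrow(out2), 0L)
  # edge support is the maximum supporting weight
  ann3 <- ann
  ann3$pfam_ids <- c("PF00487", "PF00487")
  out3 <- attach_enzyme_support(pairs, nodes, net, ann3, rules,
                                cluster_restricted = FALSE)
  expect_equal(unique(out3$edge_support), 0.9)
})

test_that("the reaction network keeps multiplicity and provenance", {
  edges <- data.frame(
    substrate_node = c("A", "B", "C", "A"),
    product_node = c("B", "C", "D", "B"),
    rule_id = c("r1", "r2", "r3", "r9"), orientation = "forward",
    transition = 1, delta = 1, edge_support = c(0.5, 0.6, 0.7, 0.4),
    n_support = 1L, enzyme_support = "t|p|0.9|0.5",
    stringsAsFactors = FALSE)
  nodes <- two_node_setup(c(100, 101, 102, 103), ids = c("A", "B", "C", "D"))
  net <- build_network(edges, nodes)
  expect_identical(nrow(net$nodes), 4L)
  expect_identical(nrow(net$edges), 4L)  # parallel A->B edges preserved
  g <- network_igraph(net)
  expect_identical(as.integer(igraph::vcount(g)), 4L)
  expect_identical(as.integer(igraph::ecount(g)), 4L)
})

dag_edges <- function(sub, prod, support, rule = NULL) {
  data.frame(substrate_node = sub, product_node = prod,
             rule_id = rule %||% sprintf("r%d", seq_along(sub)),
             orientation = "forward", transition = 1, delta = 1,
             edge_support = support, n_support = 1L,
             enzyme_support = "t|p|1|1", stringsAsFactors = FALSE)
}

test_that("cycle resolution removes the weakest retreating/equidistant edge", {
  nodes <- two_node_setup(c(1, 2, 3), ids = c("A", "B", "C"))
  tri <- build_network(dag_edges(c("A", "B", "C"), c("B", "C", "A"),
                                 c(0.9, 0.8, 0.7)), nodes)
  dag <- to_dag(tri, "A")
  expect_identical(nrow(dag$edges), 2L)
  expect_false(any(dag$edges$substrate_node == "C" &
                     dag$edges$product_node == "A"))
  # a chain is already a DAG
  chain <- build_network(dag_edges(c("A", "B"), c("B", "C"), c(1, 1)),
                         nodes)
  expect_identical(nrow(to_dag(chain, "A")$edges), 2L)
  # reciprocal equidistant edges: the weaker one goes
  nodes4 <- two_node_setup(c(1, 2, 3), ids = c("R", "X", "Y"))
  recip <- build_network(
    dag_edges(c("R", "R", "X", "Y"), c("X", "Y", "Y", "X"),
              c(1, 1, 0.6, 0.4)), nodes4)
  dag2 <- to_dag(recip, "R")
  expect_false(any(dag2$edges$edge_support == 0.4))
  expect_true(any(dag2$edges$substrate_node == "X" &
                    dag2$edges$product_node == "Y"))
  expect_error(to_dag(tri, "missing"), "not in network")
})

test_that("DAG reduction is acyclic on random multigraphs", {
  withr::local_seed(99)
  for (trial in 1:25) {
    n <- sample(4:9, 1)
    ids <- paste0("n", seq_len(n))
    m <- sample(5:20, 1)
    edges <- dag_edges(sample(ids, m, replace = TRUE),
                       sample(ids, m, replace = TRUE),
                       runif(m))
    edges <- edges[edges$substrate_node != edges$product_node, ,
                   drop = FALSE]
    if (nrow(edges) == 0) next
    net <- build_network(edges, two_node_setup(seq_len(n), ids))
    root <- edges$substrate_node[1]
    dag <- to_dag(net, root)
    if (nrow(dag$edges) == 0) next
    g <- igraph::graph_from_data_frame(
      dag$edges[, c("substrate_node", "product_node")])
    expect_true(igraph::is_dag(g))
  }
})

test_that("longest path maximizes length, then support, deterministically", {
  nodes <- two_node_setup(1:6, ids = c("A", "B", "C", "D", "E", "F"))
  chain <- build_network(dag_edges(c("A", "B", "C"), c("B", "C", "D"),
                                   c(1, 1, 1)), nodes)
  lp <- longest_path(to_dag(chain, "A"))
  expect_identical(lp$nodes, c("A", "B", "C", "D"))
  expect_identical(lp$length, 3L)
  # two branches of length 2 and 3
  branches <- build_network(
    dag_edges(c("A", "B", "A", "D", "E"), c("B", "C", "D", "E", "F"),
              rep(1, 5)), nodes)
  expect_identical(longest_path(to_dag(branches, "A"))$nodes,
                   c("A", "D", "E", "F"))
  # equal-length branches resolved by summed support
  tie <- build_network(
    dag_edges(c("A", "B", "A", "D"), c("B", "C", "D", "E"),
              c(0.9, 0.9, 0.5, 0.5)), nodes)
  expect_identical(longest_path(to_dag(tie, "A"))$nodes, c("A", "B", "C"))
})

test_that("mass is conserved on every retained toy network edge", {
  run <- toy_run()
  net <- run$res$network
  mass_of <- setNames(net$nodes$mass, net$nodes$node_id)
  tol <- 20e-6 * max(net$nodes$mass)
  for (k in seq_len(nrow(net$edges))) {
    expect_lte(abs(mass_of[[net$edges$product_node[k]]] -
                     mass_of[[net$edges$substrate_node[k]]] -
                     net$edges$transition[k]), tol)
  }
})

# ---- structure-aware operations (cheminformatics backend) -----------------

test_that("rule application generates the expected products", {
  expect_true(chem_backend_available())
  arom_oh <- rules_from_table(local({
    t <- hydrox_rule_table(rule_id = "arom_oh")
    t$smarts <- "[cH:1]>>[c:1]O"
    t$substrate_mass <- 78.04695
    t$product_mass <- 78.04695 + 15.994915
    t
  }))[[1]]
  prods <- apply_rule("c1ccccc1", arom_oh)
  expect_identical(prods[["c1ccccc1"]], "Oc1ccccc1")
  # a template with no eligible site yields no products, not an error
  desat <- rules_from_table(local({
    t <- hydrox_rule_table(rule_id = "desat")
    t$smarts <- "[CH2:1][CH2:2]>>[CH1:1]=[CH1:2]"
    t$substrate_mass <- 16.0313
    t$product_mass <- 16.0313 - 2.01565
    t
  }))[[1]]
  expect_length(apply_rule("C", desat)[["C"]], 0)
})

test_that("flavanone 2-hydroxylation converts naringenin as characterized", {
  expect_true(chem_backend_available())
  naringenin <- "O=C1CC(c2ccc(O)cc2)Oc2cc(O)cc(O)c21"
  f2h <- rules_from_table(local({
    t <- hydrox_rule_table(rule_id = "flavanone_2_hydroxylase")
    t$smarts <- "[O:1][CH1:2][c:3]>>[O:1][C:2](O)[c:3]"
    t$substrate_mass <- 272.068473
    t$product_mass <- 272.068473 + 15.994915
    t
  }))[[1]]
  prods <- apply_rule(naringenin, f2h)[[naringenin]]
  expect_true("O=C1CC(O)(c2ccc(O)cc2)Oc2cc(O)cc(O)c21" %in% prods)
})

test_that("prescreening is equivalent to brute-force rule matching", {
  expect_true(chem_backend_available())
  structures <- prescreen_structures()
  rules <- rules_from_table(prescreen_rule_table(), tier = "strict")
  expect_gte(length(rules), 28)
  pre <- substructure_prescreen(structures, default_hierarchy(rules))
  adm <- admissible_rules(pre)
  templates <- vapply(rules, function(r)
    sub(">>.*$", "", r$smarts), character(1))
  brute <- pathomics:::smarts_match(structures, unname(templates))
  for (s in structures) {
    brute_hits <- names(rules)[which(brute[s, ])]
    expect_identical(sort(adm[[s]]), sort(brute_hits))
  }
  # benzene carries no nitrogen: every N-gated key is skipped
  n_keys <- pre[["c1ccccc1"]]
  expect_false("elem:N" %in% n_keys)
  expect_true("elem:C" %in% n_keys)
  expect_identical(substructure_prescreen(character(0),
                                          default_hierarchy(rules)),
                   setNames(list(), character(0)))
})

test_that("iterated prediction is monotone and reaches the fixpoint", {
  expect_true(chem_backend_available())
  run <- toy_run()
  toy <- run$toy
  res <- run$res
  net1 <- res$network
  active <- res$networks[["10"]]
  net2 <- iterate_prediction(net1, toy$rules, active, toy$annotations,
                             res$clusters, cluster_restricted = TRUE,
                             rounds = 2)
  expect_gte(nrow(net2$edges), nrow(net1$edges))
  expect_gte(nrow(net2$nodes), nrow(net1$nodes))
})
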