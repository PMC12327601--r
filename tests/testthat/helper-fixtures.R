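# Shared fixture builders and brute-force oracles for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny feature table / expression matrix -------------------------------------

tiny_features <- function(ids = c("F1", "F2", "F3"),
                          mz = c(181.07082, 197.06573, 151.0),
                          samples = paste0("s", 1:4)) {
  ab <- matrix(seq_len(length(ids) * length(samples)),
               nrow = length(ids), dimnames = list(NULL, samples))
  feature_table(ids, mz, ab, rt = seq_along(ids) * 10)
}

tiny_expression <- function(n_tx = 5, samples = paste0("s", 1:6)) {
  m <- matrix(rnorm(n_tx * length(samples), 10), nrow = n_tx,
              dimnames = list(paste0("T", seq_len(n_tx)), samples))
  expression_matrix(abs(m))
}

# small weighted networks -----------------------------------------------------

clique_edges <- function(nodes, weight = 1) {
  idx <- t(combn(nodes, 2))
  data.frame(node_a = idx[, 1], node_b = idx[, 2], weight = weight,
             stringsAsFactors = FALSE)
}

# exhaustive cohesiveness maximum over all subsets of size >= min_size
brute_force_best_cohesiveness <- function(edges, min_size = 3,
                                          penalty = 2) {
  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  best <- 0
  for (k in min_size:length(nodes)) {
    sets <- combn(nodes, k, simplify = FALSE)
    for (s in sets) best <- max(best, cohesiveness(s, edges, penalty))
  }
  best
}

# rule association tables ------------------------------------------------------

hydrox_rule_table <- function(rule_id = "hydrox", pfam = "PF00067",
                              tier = "strict", direction = "both",
                              substrate_mass = 180.06339) {
  data.frame(rule_id = rule_id, reaction_ids = "RXN1",
             smarts = "[CH3:1]>>[CH2:1]O", diameter = 2L,
             direction = direction, substrate_mass = substrate_mass,
             product_mass = substrate_mass + 15.994915,
             pfam_id = pfam, ec_number = "1.14.14.1", tier = tier,
             taxon = "Viridiplantae", stringsAsFactors = FALSE)
}

# brute-force Mann-Whitney: enumerate every assignment of the pooled values
# to group 1 (exact two-sided p on U, average ranks)
brute_force_mw <- function(x, y) {
  n1 <- length(x)
  pool <- c(x, y)
  n <- length(pool)
  ranks <- rank(pool, ties.method = "average")
  u_of <- function(ix) sum(ranks[ix]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  sets <- combn(n, n1, simplify = FALSE)
  us <- vapply(sets, u_of, numeric(1))
  list(U = u_obs,
       p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}

# linear-scan transition lookup oracle
linear_scan_lookup <- function(rules, delta, tolerance) {
  hits <- character(0)
  for (r in rules) {
    ts <- r$mass_transition
    if (identical(r$direction, "both")) ts <- c(ts, -ts)
    if (any(abs(ts - delta) <= tolerance)) hits <- c(hits, r$rule_id)
  }
  sort(unique(hits))
}

# structures and rules for prescreen-vs-brute-force equivalence ---------------

prescreen_structures <- function() {
  c("c1ccccc1", "Oc1ccccc1", "Nc1ccccc1", "c1ccncc1", "Cc1ccccc1",
    "CCO", "CC(=O)O", "CCN", "CC=C", "C#N",
    "CCCCCC", "OCCO", "NCCN", "CSC", "CC(N)C(=O)O",
    "c1ccc2ccccc2c1", "OC(=O)c1ccccc1", "CNC", "CC(C)=O", "C1CCOC1")
}

prescreen_rule_table <- function() {
  smarts <- c(
    "[CH3:1]>>[CH2:1]O", "[CH2:1]>>[CH1:1]O", "[cH:1]>>[c:1]O",
    "[CH2:1][CH2:2]>>[CH1:1]=[CH1:2]", "[OX2H:1]>>[O:1]C",
    "[NX3;H2:1]>>[N:1]C", "[C:1](=[O:2])[OH]>>[C:1](=[O:2])OC",
    "[cH:1]>>[c:1]N", "[CH3:1]>>[CH2:1]N", "[OH:1][CH2:2]>>[O:1]=[CH1:2]",
    "[N:1][CH3:2]>>[N:1][CH2:2]O", "[S:1][CH3:2]>>[S:1][CH2:2]O",
    "[c:1][OH:2]>>[c:1][O:2]C", "[C:1]#[N:2]>>[C:1](=O)[NH2:2]",
    "[CH1:1]=[CH2:2]>>[CH2:1][CH2:2]O", "[n:1]>>[n:1]",
    "[C:1](=[O:2])[CH3:3]>>[C:1](=[O:2])[CH2:3]O",
    "[NX3;H1:1]([CH3:2])>>[N:1][CH2:2]O", "[OX2:1]([CH2:2])>>[O:1]=[C:2]",
    "[cH:1][cH:2]>>[c:1](O)[c:2]O",
    "[CH2:1][OH:2]>>[CH1:1]=[O:2]", "[NH2:1][CH2:2]>>[N:1]=[CH1:2]",
    "[CH3:1][S:2]>>[CH2:1](O)[S:2]", "[c:1][CH3:2]>>[c:1][CH2:2]O",
    "[C:1](=[O:2])>>[CH1:1][OH:2]", "[N:1]=[C:2]>>[N:1][CH1:2]",
    "[O:1]=[C:2][NH2:3]>>[O:1]=[C:2][NH1:3]C",
    "[CH1:1]([OH:2])>>[C:1](=[O:2])", "[cH:1][n:2]>>[c:1](O)[n:2]",
    "[CH2:1][NH2:2]>>[CH2:1][NH1:2]C")
  n <- length(smarts)
  data.frame(rule_id = sprintf("pr%02d", seq_len(n)),
             reaction_ids = sprintf("R%02d", seq_len(n)), smarts = smarts,
             diameter = 2L, direction = "forward",
             substrate_mass = 100, product_mass = 100 + seq_len(n) * 0.5,
             pfam_id = sprintf("PF%05d", seq_len(n)),
             ec_number = "1.1.1.1", tier = "strict", taxon = "any",
             stringsAsFactors = FALSE)
}

# shared toy pipeline run (memoised; several tests inspect it)
toy_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      toy <- toy_dataset(seed = 1)
      res <- suppressMessages(
        run_pipeline(toy$features, toy$expression, toy$annotations,
                     toy$rules, toy$metabolite_db, toy$adducts))
      cache <<- list(toy = toy, res = res)
    }
    cache
  }
})
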