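# Reaction-network construction and pathway extraction.
#
# Measured mass features (under their adduct hypotheses) become nodes with
# neutral masses; ordered node pairs whose mass difference matches a rule's
# mass transition become candidate reactions; candidates survive only with
# enzyme support (a correlated / co-clustered transcript carrying a Pfam
# associated to the rule). Unmeasured "ghost" intermediates can bridge two
# measured signatures when a two-rule transition sum explains their mass
# difference. Rooted subnetworks are reduced to DAGs and the longest
# root-originating path is reported as the pathway prediction.

#' Build mass-signature nodes from annotated features
#'
#' One node per (feature, adduct hypothesis), deduplicated by neutral mass
#' within each feature; features without annotation fall back to a default
#' adduct hypothesis so they can still anchor reactions. Structure SMILES
#' from the metabolite table are attached where known.
#'
#' @param features a `FeatureTable`.
#' @param annotations data.frame from [annotate_features()].
#' @param db metabolite table (for structure SMILES); optional.
#' @param fallback_adduct adduct spec row applied to unannotated features
#'   (default the shipped \code{[M+H]+}); NULL to skip them.
#' @return data.frame of `MassSignatureNode`s: `node_id`, `kind`, `mass`,
#'   `source_feature`, `structures` (semicolon-collapsed SMILES, may be "").
#' @export
mass_nodes <- function(features, annotations, db = NULL,
                       fallback_adduct = NULL) {
  if (is.null(fallback_adduct)) {
    ad <- default_adducts()
    fallback_adduct <- ad[ad$name == "[M+H]+", ]
  }
  smiles_of <- function(ids) {
    if (is.null(db) || !"smiles" %in% names(db)) return("")
    sm <- db$smiles[match(ids, db$structure_id)]
    paste(unique(sm[!is.na(sm)]), collapse = ";")
  }
  rows <- list()
  for (fid in features$feature_id) {
    ann <- annotations[annotations$feature_id == fid, , drop = FALSE]
    if (nrow(ann) > 0) {
      for (aname in unique(ann$adduct_name)) {
        sub <- ann[ann$adduct_name == aname, , drop = FALSE]
        rows[[length(rows) + 1]] <- data.frame(
          node_id = paste0(fid, "@", aname), kind = "measured",
          mass = sub$neutral_mass[1], source_feature = fid,
          structures = smiles_of(sub$structure_id),
          stringsAsFactors = FALSE)
      }
    } else if (!is.null(fallback_adduct) && nrow(fallback_adduct) > 0) {
      m <- neutral_mass(features$mz[features$feature_id == fid],
                        fallback_adduct)
      if (!is.na(m)) {
        rows[[length(rows) + 1]] <- data.frame(
          node_id = paste0(fid, "@", fallback_adduct$name),
          kind = "measured", mass = m, source_feature = fid,
          structures = "", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(node_id = character(0), kind = character(0),
                      mass = numeric(0), source_feature = character(0),
                      structures = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  # deduplicate multiple adduct hypotheses landing on one neutral mass
  key <- paste(out$source_feature, round(out$mass, 6))
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[lex_order(out$node_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_pairs <- function() {
  data.frame(substrate_node = character(0), product_node = character(0),
             rule_id = character(0), orientation = character(0),
             transition = numeric(0), delta = numeric(0),
             stringsAsFactors = FALSE)
}

#' Match node pairs whose mass difference a reaction rule explains
#'
#' All ordered node pairs (i, j) with
#' `|mass(j) - mass(i) - transition| <= tolerance` for some indexed
#' transition become candidate substrate -> product assignments. A
#' bidirectional rule is indexed under both signs, so such a pair is
#' matched in both orientations; a pair may carry several rules.
#'
#' @param nodes node table from [mass_nodes()].
#' @param index a `TransitionIndex`.
#' @param tolerance absolute mass tolerance (Da).
#' @return data.frame of candidate pairs: `substrate_node`, `product_node`,
#'   `rule_id`, `orientation`, `transition`, `delta`.
#' @export
match_mass_pairs <- function(nodes, index, tolerance) {
  n <- nrow(nodes)
  rows <- list()
  if (n >= 2) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        if (identical(nodes$source_feature[i], nodes$source_feature[j]) &&
            !is.na(nodes$source_feature[i])) next
        delta <- nodes$mass[j] - nodes$mass[i]
        hits <- transition_lookup(index, delta, tolerance)
        if (nrow(hits) == 0) next
        rows[[length(rows) + 1]] <- data.frame(
          substrate_node = nodes$node_id[i],
          product_node = nodes$node_id[j],
          rule_id = hits$rule_id, orientation = hits$orientation,
          transition = hits$transition, delta = delta,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty_pairs())
  out <- do.call(rbind, rows)
  out <- out[lex_order(out$substrate_node, out$product_node, out$rule_id,
                       out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Insert ghost mass signatures between measured nodes
#'
#' For measured nodes A and C not linked by any single rule, if two indexed
#' transitions t1 + t2 explain `mass(C) - mass(A)` within tolerance, an
#' unmeasured intermediate ("ghost") node B is created at
#' `mass(A) + t1` with candidate edges A -> B and B -> C. At most one ghost
#' sits between two measured nodes per round. Modes: `"off"` returns the
#' input unchanged; `"auto"` bridges only node pairs where at least one end
#' received no substrate/product assignment; `"always"` tries all pairs.
#'
#' @param pairs candidate pairs from [match_mass_pairs()].
#' @param nodes node table.
#' @param index a `TransitionIndex`.
#' @param mode `"off"`, `"auto"` or `"always"`.
#' @param tolerance absolute mass tolerance (Da).
#' @return list with extended `pairs` and `nodes`.
#' @export
insert_ghosts <- function(pairs, nodes, index, mode = c("auto", "off",
                                                        "always"),
                          tolerance) {
  mode <- match.arg(mode)
  if (mode == "off") return(list(pairs = pairs, nodes = nodes))
  measured <- nodes[nodes$kind == "measured", , drop = FALSE]
  assigned <- union(pairs$substrate_node, pairs$product_node)
  linked <- paste(pairs$substrate_node, pairs$product_node)
  tab <- index$table
  new_pairs <- list()
  new_nodes <- list()
  n <- nrow(measured)
  if (n >= 2 && nrow(tab) > 0) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        a <- measured$node_id[i]
        c_ <- measured$node_id[j]
        if (paste(a, c_) %in% linked || paste(c_, a) %in% linked) next
        if (mode == "auto" && a %in% assigned && c_ %in% assigned) next
        delta <- measured$mass[j] - measured$mass[i]
        for (k in seq_len(nrow(tab))) {
          t1 <- tab$transition[k]
          rest <- transition_lookup(index, delta - t1, tolerance)
          if (nrow(rest) == 0) next
          gmass <- measured$mass[i] + t1
          if (gmass <= 0) next
          gid <- sprintf("ghost_%.4f", round(gmass, 4))
          new_nodes[[gid]] <- data.frame(
            node_id = gid, kind = "ghost", mass = gmass,
            source_feature = NA_character_, structures = "",
            stringsAsFactors = FALSE)
          new_pairs[[length(new_pairs) + 1]] <- data.frame(
            substrate_node = a, product_node = gid,
            rule_id = tab$rule_id[k], orientation = tab$orientation[k],
            transition = t1, delta = t1, stringsAsFactors = FALSE)
          new_pairs[[length(new_pairs) + 1]] <- data.frame(
            substrate_node = gid, product_node = c_,
            rule_id = rest$rule_id, orientation = rest$orientation,
            transition = rest$transition, delta = delta - t1,
            stringsAsFactors = FALSE)
          break  # one ghost per measured pair per round
        }
      }
    }
  }
  if (length(new_pairs) > 0) {
    pairs <- rbind(pairs, do.call(rbind, new_pairs))
    pairs <- pairs[!duplicated(pairs[, c("substrate_node", "product_node",
                                         "rule_id", "orientation")]), ,
                   drop = FALSE]
    pairs <- pairs[lex_order(pairs$substrate_node, pairs$product_node,
                             pairs$rule_id, pairs$orientation), ,
                   drop = FALSE]
    nodes <- rbind(nodes, do.call(rbind, new_nodes))
    nodes <- nodes[!duplicated(nodes$node_id), , drop = FALSE]
    nodes <- nodes[lex_order(nodes$node_id), , drop = FALSE]
    rownames(pairs) <- NULL
    rownames(nodes) <- NULL
  }
  list(pairs = pairs, nodes = nodes)
}

transcript_pfams <- function(annotations) {
  stats::setNames(strsplit(annotations$pfam_ids, ";", fixed = TRUE),
                  annotations$transcript_id)
}

#' Attach enzyme support to candidate reaction pairs
#'
#' A candidate pair becomes a reaction edge only if at least one transcript
#' (i) is correlated with the substrate or product feature in the active
#' decay-weighted network (and, in cluster-restricted mode, shares a
#' functional cluster with it), and (ii) carries a Pfam associated with the
#' pair's rule at the active tier. `edge_support` is the maximum supporting
#' correlation edge weight. Unsupported pairs are dropped.
#'
#' @param pairs candidate pairs (possibly ghost-extended).
#' @param nodes node table (maps nodes to source features).
#' @param net_edges weighted edge table of the active decay-rate network.
#' @param annotations transcript annotation table: `transcript_id`,
#'   `pfam_ids` (semicolon-separated), `category`.
#' @param rules named list of `ReactionRule`s.
#' @param clusters functional-cluster data.frame (needed when
#'   `cluster_restricted`).
#' @param cluster_restricted require transcript and feature to co-occur in
#'   a functional cluster (default TRUE).
#' @return data.frame of `ReactionEdge`s: pair columns plus
#'   `edge_support`, `n_support`, `enzyme_support`
#'   ("transcript|pfam|r|weight", semicolon-separated).
#' @export
attach_enzyme_support <- function(pairs, nodes, net_edges, annotations,
                                  rules, clusters = NULL,
                                  cluster_restricted = TRUE) {
  if (cluster_restricted && is.null(clusters)) {
    stop2("cluster_restricted = TRUE needs a cluster table")
  }
  pf_map <- transcript_pfams(annotations)
  feat_of <- stats::setNames(nodes$source_feature, nodes$node_id)
  cluster_members <- if (!is.null(clusters) && nrow(clusters) > 0) {
    lapply(clusters$members, members_of)
  } else list()
  co_clustered <- function(tx, feat) {
    any(vapply(cluster_members, function(m) tx %in% m && feat %in% m,
               logical(1)))
  }
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    rule <- rules[[pairs$rule_id[k]]]
    if (is.null(rule)) next
    rule_pfams <- unique(rule$associations$pfam_id)
    feats <- unique(stats::na.omit(c(feat_of[[pairs$substrate_node[k]]],
                                     feat_of[[pairs$product_node[k]]])))
    if (length(feats) == 0) next
    cand <- net_edges[net_edges$feature_id %in% feats, , drop = FALSE]
    if (nrow(cand) == 0) next
    sup <- list()
    for (e in seq_len(nrow(cand))) {
      tx <- cand$transcript_id[e]
      pf <- intersect(pf_map[[tx]] %||% character(0), rule_pfams)
      if (length(pf) == 0) next
      if (cluster_restricted && !co_clustered(tx, cand$feature_id[e])) next
      sup[[length(sup) + 1]] <- data.frame(
        transcript_id = tx, pfam_id = pf[1], r = cand$r[e],
        weight = cand$weight[e], stringsAsFactors = FALSE)
    }
    if (length(sup) == 0) next
    supdf <- unique(do.call(rbind, sup))
    supdf <- supdf[lex_order(-supdf$weight, supdf$transcript_id), ,
                   drop = FALSE]
    row <- pairs[k, , drop = FALSE]
    row$edge_support <- max(supdf$weight)
    row$n_support <- nrow(supdf)
    row$enzyme_support <- paste(
      sprintf("%s|%s|%s|%s", supdf$transcript_id, supdf$pfam_id,
              fmt_num(supdf$r), fmt_num(supdf$weight)), collapse = ";")
    out[[length(out) + 1]] <- row
  }
  if (length(out) == 0) {
    ep <- empty_pairs()
    ep$edge_support <- numeric(0)
    ep$n_support <- integer(0)
    ep$enzyme_support <- character(0)
    return(ep)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble the reaction network
#'
#' A multigraph over mass-signature nodes: parallel edges (distinct rules
#' for the same pair) are allowed, and every edge keeps its rule
#' provenance, enzyme support and edge support. Only nodes referenced by at
#' least one edge (plus all measured nodes) are retained.
#'
#' @param reaction_edges data.frame from [attach_enzyme_support()].
#' @param nodes node table.
#' @return object of class `ReactionNetwork` (list: `nodes`, `edges`).
#' @export
build_network <- function(reaction_edges, nodes) {
  used <- union(reaction_edges$substrate_node, reaction_edges$product_node)
  keep <- nodes$kind == "measured" | nodes$node_id %in% used
  structure(list(nodes = nodes[keep, , drop = FALSE],
                 edges = reaction_edges),
            class = "ReactionNetwork")
}

#' @export
print.ReactionNetwork <- function(x, ...) {
  cat(sprintf("ReactionNetwork: %d nodes (%d ghost), %d edges\n",
              nrow(x$nodes), sum(x$nodes$kind == "ghost"), nrow(x$edges)))
  invisible(x)
}

#' Convert the network to an igraph object
#' @param network a `ReactionNetwork`.
#' @return an igraph directed multigraph.
#' @export
network_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("substrate_node", "product_node",
                      setdiff(names(network$edges),
                              c("substrate_node", "product_node")))],
    directed = TRUE, vertices = network$nodes)
}

bfs_distances <- function(edges, all_nodes, root) {
  nbr <- build_adjacency(data.frame(node_a = edges$substrate_node,
                                    node_b = edges$product_node,
                                    weight = 1, stringsAsFactors = FALSE))
  dist <- stats::setNames(rep(NA_real_, length(all_nodes)), all_nodes)
  dist[root] <- 0
  frontier <- root
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- unique(unlist(lapply(frontier, function(v) nbr[[v]]$to)))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# one directed cycle (as edge-row indices), or NULL; deterministic
find_cycle <- function(edges, nodes_ids) {
  adj <- split(seq_len(nrow(edges)), edges$substrate_node)
  color <- stats::setNames(rep(0L, length(nodes_ids)), nodes_ids)
  parent_edge <- stats::setNames(rep(NA_integer_, length(nodes_ids)),
                                 nodes_ids)
  cycle <- NULL
  dfs <- function(v) {
    color[v] <<- 1L
    for (ei in adj[[v]] %||% integer(0)) {
      w <- edges$product_node[ei]
      if (color[w] == 0L) {
        parent_edge[w] <<- ei
        dfs(w)
        if (!is.null(cycle)) return()
      } else if (color[w] == 1L) {
        # back edge: walk parents from v to w
        path <- ei
        u <- v
        while (u != w) {
          pe <- parent_edge[u]
          path <- c(pe, path)
          u <- edges$substrate_node[pe]
        }
        cycle <<- path
        return()
      }
    }
    color[v] <<- 2L
  }
  for (v in lex_sort(nodes_ids)) {
    if (color[v] == 0L) {
      dfs(v)
      if (!is.null(cycle)) return(cycle)
    }
  }
  NULL
}

#' Reduce a rooted subnetwork to a pathway DAG
#'
#' Breadth-first reaction distance from the root is computed on the
#' undirected skeleton; nodes unreachable from the root are dropped. Edges
#' that retreat toward the root are removed; edges advancing the distance
#' by one are kept; residual cycles (necessarily among equidistant nodes)
#' are broken by repeatedly deleting the cycle edge with minimum
#' `edge_support`, ties by lexicographically smallest
#' (substrate, product, rule). The result is acyclic and root-connected.
#'
#' @param network a `ReactionNetwork`.
#' @param root node id of the initial metabolite.
#' @return object of class `PathwayDAG` (list: `root`, `nodes`, `edges`).
#' @export
to_dag <- function(network, root) {
  if (!root %in% network$nodes$node_id) stop2("root '%s' not in network",
                                              root)
  edges <- network$edges
  dist <- bfs_distances(edges, network$nodes$node_id, root)
  keep_nodes <- names(dist)[!is.na(dist)]
  edges <- edges[edges$substrate_node %in% keep_nodes &
                   edges$product_node %in% keep_nodes, , drop = FALSE]
  dd <- dist[edges$product_node] - dist[edges$substrate_node]
  edges <- edges[dd >= 0, , drop = FALSE]  # drop retreating edges
  repeat {
    cyc <- find_cycle(edges, keep_nodes)
    if (is.null(cyc)) break
    ce <- edges[cyc, , drop = FALSE]
    pick <- cyc[lex_order(ce$edge_support, ce$substrate_node,
                          ce$product_node, ce$rule_id)][1]
    edges <- edges[-pick, , drop = FALSE]
  }
  # after cycle removal some nodes may no longer connect to the root
  dist2 <- bfs_distances(edges, keep_nodes, root)
  keep_nodes <- names(dist2)[!is.na(dist2)]
  edges <- edges[edges$substrate_node %in% keep_nodes &
                   edges$product_node %in% keep_nodes, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(root = root,
                 nodes = network$nodes[network$nodes$node_id %in%
                                         keep_nodes, , drop = FALSE],
                 edges = edges),
            class = "PathwayDAG")
}

#' @export
print.PathwayDAG <- function(x, ...) {
  cat(sprintf("PathwayDAG rooted at %s: %d nodes, %d edges\n",
              x$root, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Longest root-originating path of a pathway DAG
#'
#' Maximum-edge-count path starting at the root, by dynamic programming in
#' topological order. Ties are broken by larger summed `edge_support`,
#' then by lexicographically smallest node sequence, so the prediction is
#' deterministic.
#'
#' @param dag a `PathwayDAG`.
#' @return list with `nodes` (ordered node ids), `rules` (rule id per
#'   step), `edges` (the edge rows used) and `length` (edge count).
#' @export
longest_path <- function(dag) {
  nodes <- dag$nodes$node_id
  edges <- dag$edges
  # Kahn topological order with lexicographic tie-break
  indeg <- stats::setNames(rep(0L, length(nodes)), nodes)
  tb <- table(edges$product_node)
  indeg[names(tb)] <- as.integer(tb)
  avail <- lex_sort(names(indeg)[indeg == 0L])
  topo <- character(0)
  adj <- split(seq_len(nrow(edges)), edges$substrate_node)
  while (length(avail) > 0) {
    v <- avail[1]
    avail <- avail[-1]
    topo <- c(topo, v)
    for (ei in adj[[v]] %||% integer(0)) {
      w <- edges$product_node[ei]
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- lex_sort(c(avail, w))
    }
  }
  if (length(topo) < length(nodes)) stop2("graph is not acyclic")

  len <- stats::setNames(rep(-Inf, length(nodes)), nodes)
  sup <- stats::setNames(rep(0, length(nodes)), nodes)
  path <- stats::setNames(vector("list", length(nodes)), nodes)
  epath <- stats::setNames(vector("list", length(nodes)), nodes)
  len[dag$root] <- 0
  path[[dag$root]] <- dag$root
  for (v in topo) {
    if (!is.finite(len[v])) next
    for (ei in adj[[v]] %||% integer(0)) {
      w <- edges$product_node[ei]
      cand_len <- len[v] + 1
      cand_sup <- sup[v] + edges$edge_support[ei]
      cand_path <- c(path[[v]], w)
      better <- cand_len > len[w] ||
        (cand_len == len[w] && cand_sup > sup[w] + 1e-12) ||
        (cand_len == len[w] && abs(cand_sup - sup[w]) <= 1e-12 &&
           paste(cand_path, collapse = "\r") <
           paste(path[[w]] %||% "￿", collapse = "\r"))
      if (better) {
        len[w] <- cand_len
        sup[w] <- cand_sup
        path[[w]] <- cand_path
        epath[[w]] <- c(epath[[v]], ei)
      }
    }
  }
  finite <- names(len)[is.finite(len)]
  best <- finite[lex_order(-len[finite], -sup[finite],
                           vapply(path[finite], paste, character(1),
                                  collapse = "\r"))][1]
  used <- edges[epath[[best]] %||% integer(0), , drop = FALSE]
  rownames(used) <- NULL
  list(nodes = path[[best]], rules = used$rule_id, edges = used,
       length = as.integer(len[best]))
}

reverse_network <- function(network) {
  ed <- network$edges
  tmp <- ed$substrate_node
  ed$substrate_node <- ed$product_node
  ed$product_node <- tmp
  structure(list(nodes = network$nodes, edges = ed),
            class = "ReactionNetwork")
}

#' Pathway predictions for an initial metabolite
#'
#' Runs the DAG reduction and longest-path extraction rooted at the given
#' node, then again on the reversed network rooted at the terminal node of
#' the forward prediction — yielding the two directional predictions
#' (biosynthetic route away from the metabolite, and route leading to it).
#'
#' @param network a `ReactionNetwork`.
#' @param root node id of the initial metabolite.
#' @return list with elements `forward` and `reverse` (each as returned by
#'   [longest_path()]; `reverse` is NULL when the forward path has no
#'   edges).
#' @export
pathway_predictions <- function(network, root) {
  fwd <- longest_path(to_dag(network, root))
  rev <- NULL
  if (fwd$length > 0) {
    terminal <- fwd$nodes[length(fwd$nodes)]
    rev <- longest_path(to_dag(reverse_network(network), terminal))
  }
  list(forward = fwd, reverse = rev)
}

#' Apply a reaction rule to substrate structures
#'
#' Runs the rule's single-substrate reaction SMARTS on each substrate
#' through the cheminformatics backend; products are canonicalized and
#' deduplicated, and any product whose monoisotopic mass does not equal
#' substrate mass + mass transition within `mass_tolerance` is discarded
#' (and logged). A non-matching template yields an empty product set, not
#' an error.
#'
#' @param smiles character vector of substrate SMILES.
#' @param rule a `ReactionRule`.
#' @param mass_tolerance Da (default 0.005).
#' @return named list: substrate SMILES -> character vector of product
#'   SMILES.
#' @export
apply_rule <- function(smiles, rule, mass_tolerance = 0.005) {
  res <- chem_call(list(op = "apply_rule", smiles = as.list(smiles),
                        rxn_smarts = rule$smarts))
  info <- smiles_info(smiles)
  out <- vector("list", length(smiles))
  names(out) <- smiles
  for (i in seq_along(smiles)) {
    r <- res$results[[i]]
    if (!is.null(r$error)) {
      pk_log("apply_rule(%s): %s", rule$rule_id, r$error)
      out[[i]] <- character(0)
      next
    }
    prods <- unlist(r$products) %||% character(0)
    masses <- unlist(r$masses) %||% numeric(0)
    expected <- info$mass[i] + rule$mass_transition
    ok <- abs(masses - expected) <= mass_tolerance
    if (any(!ok)) {
      pk_log("apply_rule(%s): discarded %d product(s) violating the mass transition",
             rule$rule_id, sum(!ok))
    }
    out[[i]] <- prods[ok]
  }
  out
}

#' Divide-and-conquer substructure prescreen
#'
#' Structures are tested against a hierarchy of substructure keys ordered
#' from cheap to specific (atom presence, then bond patterns, then rule
#' reactant templates): a key is tested only when all of its parent keys
#' passed, so most rule templates are never matched against most
#' structures. With a hierarchy whose parents are necessary conditions of
#' their children (as built by [default_hierarchy()]), the admissible rule
#' set is identical to brute-force matching of every rule template.
#'
#' @param structures character vector of SMILES.
#' @param hierarchy data.frame `key`, `smarts`, `parents`
#'   (semicolon-separated parent keys, "" for roots), in an order where
#'   parents precede children.
#' @return named list: structure -> character vector of admissible keys.
#'   Unparseable structures are skipped with a warning.
#' @export
substructure_prescreen <- function(structures, hierarchy) {
  if (length(structures) == 0) return(stats::setNames(list(), character(0)))
  info <- smiles_info(structures)
  bad <- structures[!info$valid]
  if (length(bad) > 0) {
    warning(sprintf("skipped %d unparseable structure(s)", length(bad)),
            call. = FALSE)
  }
  ok_structures <- structures[info$valid]
  admissible <- stats::setNames(
    rep(list(character(0)), length(ok_structures)), ok_structures)
  parents <- strsplit(hierarchy$parents, ";", fixed = TRUE)
  for (k in seq_len(nrow(hierarchy))) {
    par <- parents[[k]]
    par <- par[nzchar(par)]
    cand <- names(admissible)[vapply(admissible, function(a)
      all(par %in% a), logical(1))]
    if (length(cand) == 0) next
    m <- smarts_match(cand, hierarchy$smarts[k])
    hit <- cand[which(m[, 1])]
    for (s in hit) admissible[[s]] <- c(admissible[[s]], hierarchy$key[k])
  }
  admissible
}

# conservative required-element extraction from a SMARTS reactant template
required_elements <- function(template) {
  elems <- character(0)
  # bracket atoms: only unambiguous single-primitive expressions
  brackets <- regmatches(template,
                         gregexpr("\\[[^]]*\\]", template))[[1]]
  stripped <- gsub("\\[|\\]|:[0-9]+", "", brackets)
  for (b in stripped) {
    if (grepl("[,;!&$*]", b)) next
    if (grepl("^#([0-9]+)", b)) {
      num <- as.integer(sub("^#([0-9]+).*$", "\\1", b))
      sym <- names(ELEMENT_NUMBERS)[match(num, ELEMENT_NUMBERS)]
      if (!is.na(sym)) elems <- c(elems, sym)
    } else if (grepl("^(Cl|Br|[BCNOSPFI]|[cnosp])", b)) {
      sym <- regmatches(b, regexpr("^(Cl|Br|[BCNOSPFI]|[cnosp])", b))
      elems <- c(elems, toupper(sym))
    }
  }
  # atoms written outside brackets
  outside <- gsub("\\[[^]]*\\]", "", template)
  toks <- regmatches(outside,
                     gregexpr("Cl|Br|[BCNOSPFI]|[cnosp]", outside))[[1]]
  unique(c(elems, toupper(toks)))
}

ELEMENT_NUMBERS <- c(B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, P = 15L,
                     S = 16L, Cl = 17L, Br = 35L, I = 53L)

#' Default substructure hierarchy for a rule set
#'
#' Level 1: presence of each element any rule's reactant template requires
#' (atomic-number SMARTS, so aromatic and aliphatic forms both count).
#' Level 2: one key per rule reactant template, gated on its required
#' elements. The gates are necessary conditions, so prescreening never
#' loses a genuinely applicable rule.
#'
#' @param rules list of `ReactionRule`s.
#' @return hierarchy data.frame for [substructure_prescreen()]; rule keys
#'   are named `rule:<rule_id>`.
#' @export
default_hierarchy <- function(rules) {
  req <- lapply(rules, function(r)
    required_elements(reactant_template(r$smarts)))
  elems <- lex_sort(unique(unlist(req)))
  h1 <- data.frame(key = paste0("elem:", elems),
                   smarts = sprintf("[#%d]", ELEMENT_NUMBERS[elems]),
                   parents = rep("", length(elems)),
                   stringsAsFactors = FALSE)
  h2 <- data.frame(
    key = paste0("rule:", vapply(rules, `[[`, character(1), "rule_id")),
    smarts = vapply(rules, function(r) reactant_template(r$smarts),
                    character(1)),
    parents = vapply(req, function(e) {
      if (length(e) == 0) "" else paste0("elem:", e, collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)
  rbind(h1, h2)
}

#' Admissible rules per structure after prescreening
#' @param prescreen result of [substructure_prescreen()] run on a
#'   [default_hierarchy()].
#' @return named list: structure -> character vector of rule ids whose
#'   reactant template matched.
#' @export
admissible_rules <- function(prescreen) {
  lapply(prescreen, function(keys) {
    sub("^rule:", "", keys[startsWith(keys, "rule:")])
  })
}

#' Iterate in-silico product generation over the network
#'
#' Each round applies every admissible rule (after substructure
#' prescreening) to the structures attached to network nodes, maps product
#' masses back onto existing nodes within tolerance, and proposes the new
#' substrate -> product links as candidate pairs that must pass the same
#' enzyme-support gate as measured pairs. Product structures landing on a
#' node extend that node's structure list. The network grows monotonically;
#' iteration stops at a fixpoint or after `rounds` rounds.
#'
#' @param network a `ReactionNetwork`.
#' @param rules named list of `ReactionRule`s.
#' @param net_edges,annotations,clusters,cluster_restricted passed to
#'   [attach_enzyme_support()].
#' @param rounds maximum rounds (>= 1).
#' @param tolerance mass tolerance (Da) for mapping products onto nodes.
#' @return the extended `ReactionNetwork`.
#' @export
iterate_prediction <- function(network, rules, net_edges, annotations,
                               clusters = NULL, cluster_restricted = TRUE,
                               rounds = 1, tolerance = 0.002) {
  stopifnot(rounds >= 1)
  for (round in seq_len(rounds)) {
    nodes <- network$nodes
    structs <- unique(unlist(strsplit(nodes$structures, ";", fixed = TRUE)))
    structs <- structs[nzchar(structs)]
    if (length(structs) == 0) break
    adm <- admissible_rules(
      substructure_prescreen(structs, default_hierarchy(rules)))
    new_pairs <- list()
    changed <- FALSE
    for (s in names(adm)) {
      from_nodes <- nodes$node_id[vapply(
        strsplit(nodes$structures, ";", fixed = TRUE),
        function(v) s %in% v, logical(1))]
      for (rid in adm[[s]]) {
        prods <- apply_rule(s, rules[[rid]])[[s]]
        if (length(prods) == 0) next
        pm <- smiles_info(prods)
        for (pi in seq_along(prods)) {
          hit <- which(abs(nodes$mass - pm$mass[pi]) <= tolerance)
          for (hn in hit) {
            for (fn in from_nodes) {
              if (fn == nodes$node_id[hn]) next
              new_pairs[[length(new_pairs) + 1]] <- data.frame(
                substrate_node = fn, product_node = nodes$node_id[hn],
                rule_id = rid, orientation = "forward",
                transition = rules[[rid]]$mass_transition,
                delta = nodes$mass[hn] -
                  nodes$mass[nodes$node_id == fn],
                stringsAsFactors = FALSE)
            }
            cur <- strsplit(nodes$structures[hn], ";", fixed = TRUE)[[1]]
            if (!prods[pi] %in% cur) {
              nodes$structures[hn] <- paste(c(cur[nzchar(cur)], prods[pi]),
                                            collapse = ";")
              changed <- TRUE
            }
          }
        }
      }
    }
    network$nodes <- nodes
    if (length(new_pairs) > 0) {
      cand <- unique(do.call(rbind, new_pairs))
      supported <- attach_enzyme_support(
        cand, nodes, net_edges, annotations, rules, clusters,
        cluster_restricted = cluster_restricted)
      key_old <- paste(network$edges$substrate_node,
                       network$edges$product_node, network$edges$rule_id)
      fresh <- supported[!paste(supported$substrate_node,
                                supported$product_node,
                                supported$rule_id) %in% key_old, ,
                         drop = FALSE]
      if (nrow(fresh) > 0) {
        network$edges <- rbind(network$edges, fresh)
        network$edges <- network$edges[
          lex_order(network$edges$substrate_node,
                    network$edges$product_node,
                    network$edges$rule_id), , drop = FALSE]
        rownames(network$edges) <- NULL
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  network
}
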