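# Overlapping functional-cluster (FC) detection on decay-weighted networks.
#
# A self-contained reimplementation of cohesiveness-based overlapping graph
# clustering (the ClusterONE procedure): grow candidate clusters greedily
# from high-degree seeds so that cohesiveness
#   f(C) = w_in(C) / (w_in(C) + w_bound(C) + penalty * |C|)
# improves, merge candidates whose overlap score
#   omega(A, B) = |A n B|^2 / (|A| |B|)
# reaches a threshold, and discard small clusters. Reported functional
# clusters must mix node types (>= 1 transcript and >= 1 mass feature);
# pure-transcript clusters are retained internally for coexpression-based
# merging.

# edges: data.frame(node_a, node_b, weight). Internal normalized form.
as_edge_df <- function(edges) {
  nms <- names(edges)
  if (all(c("transcript_id", "feature_id") %in% nms)) {
    edges <- data.frame(node_a = edges$transcript_id,
                        node_b = edges$feature_id,
                        weight = edges$weight, stringsAsFactors = FALSE)
  } else if (all(c("transcript_a", "transcript_b") %in% nms)) {
    edges <- data.frame(node_a = edges$transcript_a,
                        node_b = edges$transcript_b,
                        weight = edges$weight, stringsAsFactors = FALSE)
  } else if (!all(c("node_a", "node_b", "weight") %in% nms)) {
    stop2("edge table needs (node_a, node_b, weight) columns")
  }
  edges[, c("node_a", "node_b", "weight")]
}

# adjacency: named list node -> data.frame(other, weight)
build_adjacency <- function(edges) {
  both <- rbind(
    data.frame(from = edges$node_a, to = edges$node_b, w = edges$weight,
               stringsAsFactors = FALSE),
    data.frame(from = edges$node_b, to = edges$node_a, w = edges$weight,
               stringsAsFactors = FALSE))
  split(both[, c("to", "w")], both$from)
}

cohesiveness_of <- function(members, adj, penalty) {
  w_in <- 0
  w_bound <- 0
  inset <- stats::setNames(rep(TRUE, length(members)), members)
  for (v in members) {
    nb <- adj[[v]]
    if (is.null(nb)) next
    internal <- !is.na(inset[nb$to])
    w_in <- w_in + sum(nb$w[internal])
    w_bound <- w_bound + sum(nb$w[!internal])
  }
  w_in <- w_in / 2  # each internal edge visited from both ends
  w_in / (w_in + w_bound + penalty * length(members))
}

#' Cohesiveness of a node set in a weighted network
#'
#' `w_in / (w_in + w_bound + penalty * |C|)` where `w_in` is the total
#' weight of edges inside the set and `w_bound` the total weight of edges
#' crossing its boundary. The penalty term models unobserved edges and
#' discourages tiny clusters.
#'
#' @param members character vector of node ids.
#' @param edges edge data.frame (`node_a`, `node_b`, `weight`, or a
#'   transcript-feature edge table).
#' @param penalty per-node penalty (default 2).
#' @return cohesiveness in \[0, 1\].
#' @export
cohesiveness <- function(members, edges, penalty = 2) {
  edges <- as_edge_df(edges)
  cohesiveness_of(members, build_adjacency(edges), penalty)
}

#' Detect overlapping clusters by greedy cohesiveness growth
#'
#' Seeds are taken from nodes not yet covered by a cluster, in order of
#' decreasing weighted degree (ties broken by node id, so the result is
#' deterministic). Each seed's cluster grows by adding the adjacent node or
#' removing the member that best improves cohesiveness, until no single
#' move improves it. Candidate clusters with pairwise overlap
#' `omega >= overlap_threshold` are merged, and clusters smaller than
#' `min_size` are discarded.
#'
#' @param edges edge data.frame (see [cohesiveness()]).
#' @param min_size minimum cluster size reported (default 3).
#' @param penalty cohesiveness penalty (default 2).
#' @param overlap_threshold omega threshold for merging candidates
#'   (default 0.8).
#' @return list of clusters, each a list with `members` (sorted character
#'   vector) and `cohesiveness`.
#' @export
detect_clusters <- function(edges, min_size = 3, penalty = 2,
                            overlap_threshold = 0.8) {
  edges <- as_edge_df(edges)
  if (nrow(edges) == 0) return(list())
  adj <- build_adjacency(edges)
  wdeg <- vapply(adj, function(d) sum(d$w), numeric(1))
  seed_order <- names(wdeg)[lex_order(-wdeg, names(wdeg))]

  covered <- character(0)
  candidates <- list()
  for (seed in seed_order) {
    if (seed %in% covered) next
    members <- seed
    f <- cohesiveness_of(members, adj, penalty)
    repeat {
      ext <- lex_sort(setdiff(
        unique(unlist(lapply(members, function(v) adj[[v]]$to))), members))
      best_f <- f
      best_members <- NULL
      for (v in ext) {
        cand <- c(members, v)
        fv <- cohesiveness_of(cand, adj, penalty)
        if (fv > best_f + 1e-12) {
          best_f <- fv
          best_members <- cand
        }
      }
      if (length(members) > 1) {
        for (v in lex_sort(members)) {
          cand <- setdiff(members, v)
          fv <- cohesiveness_of(cand, adj, penalty)
          if (fv > best_f + 1e-12) {
            best_f <- fv
            best_members <- cand
          }
        }
      }
      if (is.null(best_members)) break
      members <- best_members
      f <- best_f
    }
    candidates[[length(candidates) + 1]] <- lex_sort(members)
    covered <- union(covered, members)
  }

  # merge candidates by overlap score omega(A,B) = |A n B|^2 / (|A||B|)
  n <- length(candidates)
  if (n > 1) {
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        ov <- length(intersect(candidates[[i]], candidates[[j]]))^2 /
          (length(candidates[[i]]) * length(candidates[[j]]))
        if (ov >= overlap_threshold) parent[find(j)] <- find(i)
      }
    }
    groups <- split(seq_len(n), vapply(seq_len(n), find, integer(1)))
    candidates <- lapply(groups, function(ix) {
      lex_sort(unique(unlist(candidates[ix])))
    })
  }

  keep <- Filter(function(m) length(m) >= min_size, candidates)
  keep <- keep[!duplicated(vapply(keep, paste, character(1),
                                  collapse = "\r"))]
  keep <- unname(keep[lex_order(vapply(keep, paste, character(1),
                                       collapse = "\r"))])
  lapply(keep, function(m) {
    list(members = m, cohesiveness = cohesiveness_of(m, adj, penalty))
  })
}

#' P-value of a functional cluster
#'
#' One-sided rank-sum comparison of the weights of edges inside the cluster
#' against the weights of edges that radiate out of it (internal greater).
#' Computed from the exact tie-aware null distribution of the rank sum, so
#' an all-tied configuration gives p = 1. A cluster with no boundary edges
#' has no outside comparison; its p is set to the smallest representable
#' double and flagged with attribute `no_boundary`.
#'
#' @param members character vector of node ids.
#' @param edges edge data.frame.
#' @return p-value in (0, 1\].
#' @export
cluster_pvalue <- function(members, edges) {
  edges <- as_edge_df(edges)
  a_in <- edges$node_a %in% members
  b_in <- edges$node_b %in% members
  internal <- edges$weight[a_in & b_in]
  boundary <- edges$weight[xor(a_in, b_in)]
  if (length(internal) == 0) stop2("cluster has no internal edges")
  if (length(boundary) == 0) {
    p <- .Machine$double.xmin
    attr(p, "no_boundary") <- TRUE
    return(p)
  }
  rank_sum_test(internal, boundary, alternative = "greater")$p
}

#' Attach p-values and build functional-cluster records
#'
#' @param clusters output of [detect_clusters()].
#' @param edges the network the clusters came from.
#' @param node_types named character vector mapping node id to
#'   `"transcript"` or `"feature"`.
#' @param decay_rate decay rate the network was built at (recorded).
#' @param require_mixed keep only clusters with at least one transcript and
#'   one feature (the functional-cluster reporting rule); default TRUE.
#' @return data.frame with `cluster_id`, `decay_rate`, `n_members`,
#'   `n_transcripts`, `n_features`, `cohesiveness`, `p_value`, `members`
#'   (semicolon-collapsed).
#' @export
functional_clusters <- function(clusters, edges, node_types,
                                decay_rate = NA_integer_,
                                require_mixed = TRUE) {
  rows <- lapply(clusters, function(cl) {
    ty <- node_types[cl$members]
    nt <- sum(ty == "transcript", na.rm = TRUE)
    nf <- sum(ty == "feature", na.rm = TRUE)
    if (require_mixed && (nt == 0 || nf == 0)) return(NULL)
    data.frame(decay_rate = decay_rate, n_members = length(cl$members),
               n_transcripts = nt, n_features = nf,
               cohesiveness = cl$cohesiveness,
               p_value = as.numeric(cluster_pvalue(cl$members, edges)),
               members = paste(cl$members, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(data.frame(cluster_id = integer(0), decay_rate = integer(0),
                      n_members = integer(0), n_transcripts = integer(0),
                      n_features = integer(0), cohesiveness = numeric(0),
                      p_value = numeric(0), members = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(cluster_id = seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

members_of <- function(fc_row) strsplit(fc_row, ";", fixed = TRUE)[[1]]

merge_groups <- function(n, link) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (link(i, j)) parent[find(j)] <- find(i)
      }
    }
  }
  split(seq_len(n), vapply(seq_len(n), find, integer(1)))
}

merge_cluster_table <- function(fcs, groups) {
  rows <- lapply(groups, function(ix) {
    mem <- lex_sort(unique(unlist(lapply(fcs$members[ix], members_of))))
    data.frame(source_clusters = paste(fcs$cluster_id[ix], collapse = ";"),
               n_members = length(mem),
               members = paste(mem, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[lex_order(out$members), , drop = FALSE]
  out <- cbind(data.frame(cluster_id = seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Merge functional clusters that share mass features
#'
#' Clusters connected by at least one common mass feature (transitively)
#' are unioned; provenance is kept in `source_clusters`. Idempotent.
#'
#' @param fcs data.frame from [functional_clusters()] (possibly several
#'   decay rates row-bound; `cluster_id` must be unique).
#' @param node_types named type vector (see [functional_clusters()]).
#' @return data.frame of merged clusters.
#' @export
merge_shared_feature_clusters <- function(fcs, node_types) {
  if (nrow(fcs) == 0) return(merge_cluster_table(fcs, list()))
  feat_sets <- lapply(fcs$members, function(m) {
    mm <- members_of(m)
    mm[node_types[mm] == "feature"]
  })
  groups <- merge_groups(nrow(fcs), function(i, j) {
    length(intersect(feat_sets[[i]], feat_sets[[j]])) > 0
  })
  merge_cluster_table(fcs, groups)
}

#' Merge functional clusters linked by coexpression edges
#'
#' Clusters are additionally merged when a transcript of one and a
#' transcript of the other are joined by a coexpression edge of weight at
#' least `min_weight` (or when they share a transcript).
#'
#' @param fcs cluster data.frame (as in [merge_shared_feature_clusters()]).
#' @param coexpr data.frame from [coexpression_network()].
#' @param min_weight minimum coexpression edge weight.
#' @param node_types named type vector.
#' @return data.frame of merged clusters (count never increases).
#' @export
coexpression_merge <- function(fcs, coexpr, min_weight, node_types) {
  if (nrow(fcs) == 0) return(merge_cluster_table(fcs, list()))
  strong <- coexpr[coexpr$weight >= min_weight, , drop = FALSE]
  tx_sets <- lapply(fcs$members, function(m) {
    mm <- members_of(m)
    mm[node_types[mm] == "transcript"]
  })
  groups <- merge_groups(nrow(fcs), function(i, j) {
    if (length(intersect(tx_sets[[i]], tx_sets[[j]])) > 0) return(TRUE)
    any(strong$transcript_a %in% tx_sets[[i]] &
          strong$transcript_b %in% tx_sets[[j]]) ||
      any(strong$transcript_a %in% tx_sets[[j]] &
            strong$transcript_b %in% tx_sets[[i]])
  })
  merge_cluster_table(fcs, groups)
}
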