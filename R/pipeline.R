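# Workflow configuration, the in-memory end-to-end runner, and the staged
# commands that persist intermediates in the project store.
#
# Stage order mirrors the analysis: correlate -> cluster -> annotate ->
# predict -> score -> report. Each staged command reads what it needs from
# the store, writes its outputs back, and fails with the name of the
# missing upstream command when run out of order.

#' Default run configuration
#'
#' Defaults follow the method's stated operating point: minimum |Pearson r|
#' 0.1, decay rates 5/10/25/50 with edge-weight cutoff 0.01, 20 ppm mass
#' tolerance, strict rule tier, Pfam promiscuity cutoff 6, ghost mode auto.
#'
#' @param features,expression,annotations,rules input file paths (CSV).
#' @param metabolite_db,adducts,atom_scores optional input paths (the
#'   shipped adduct table is used when `adducts` is NULL).
#' @param store project store path.
#' @param outdir report output directory.
#' @param ... overrides for any default parameter.
#' @return list of class `RunConfig`.
#' @export
default_run_config <- function(features = NULL, expression = NULL,
                               annotations = NULL, rules = NULL,
                               metabolite_db = NULL, adducts = NULL,
                               atom_scores = NULL,
                               store = "pathomics.sqlite",
                               outdir = "pathomics_out", ...) {
  cfg <- list(
    features = features, expression = expression,
    annotations = annotations, rules = rules,
    metabolite_db = metabolite_db, adducts = adducts,
    atom_scores = atom_scores, store = store, outdir = outdir,
    min_abs_r = 0.1,
    decay_rates = c(5, 10, 25, 50),
    weight_cutoff = 0.01,
    ppm = 20,
    ionization_mode = "positive",
    tier = "strict",
    taxa = NULL,
    max_reactions_per_pfam = 6,
    active_decay_rate = 10,
    ghost_mode = "auto",
    cluster_restricted = TRUE,
    rounds = 1,
    mad_rescaling = TRUE,
    min_cluster_size = 3,
    clusterone_penalty = 2,
    overlap_threshold = 0.8,
    roots = NULL,
    seed = 1)
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "RunConfig")
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return `RunConfig` (unset fields take their defaults).
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- default_run_config()
  cfg[names(vals)] <- vals
  cfg$decay_rates <- as.numeric(cfg$decay_rates)
  structure(cfg, class = "RunConfig")
}

#' Write a run configuration to YAML (round-trips through
#' [read_run_config()])
#' @param config a `RunConfig`.
#' @param path output YAML file.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

# absolute transition-matching tolerance implied by the ppm setting
transition_tolerance <- function(ppm, masses) {
  ppm * 1e-6 * max(masses)
}

#' Run the full workflow in memory
#'
#' Convenience runner over already-loaded inputs (e.g. a `ToyDataset`):
#' MAD rescaling, correlation, mutual ranks, decay-weighted networks,
#' functional clusters, adduct/ppm annotation, enzyme-supported reaction
#' matching with optional ghosts, and pathway extraction from every root.
#'
#' @param features `FeatureTable`.
#' @param expression `ExpressionMatrix`.
#' @param annotations transcript annotation data.frame.
#' @param rules named list of `ReactionRule`s (already tier-filtered).
#' @param metabolite_db metabolite table.
#' @param adducts adduct table (default: shipped table).
#' @param config a `RunConfig` for the numeric parameters.
#' @return list with `correlations`, `networks`, `clusters`, `annotations`
#'   (structure candidates), `nodes`, `reaction_edges`, `network`,
#'   `predictions` (data.frame, ranked), `paths` (list of path objects).
#' @export
run_pipeline <- function(features, expression, annotations, rules,
                         metabolite_db, adducts = NULL,
                         config = default_run_config()) {
  if (is.null(adducts)) adducts <- default_adducts()
  if (!identical(config$ionization_mode, "both")) {
    adducts <- adducts[adducts$mode == config$ionization_mode, ,
                       drop = FALSE]
  }
  al <- align_samples(features, expression)
  raw_features <- al$features
  expr <- al$expr
  feats <- al$features
  if (isTRUE(config$mad_rescaling)) {
    expr <- mad_rescale(expr)
    feats <- mad_rescale(feats)
  }
  edges <- mutual_rank(correlate_pairs(expr, feats,
                                       min_abs_r = config$min_abs_r))
  networks <- decay_weights(edges, decay_rates = config$decay_rates,
                            cutoff = config$weight_cutoff)
  active <- networks[[as.character(config$active_decay_rate)]]
  if (is.null(active)) stop2("active_decay_rate %s not among decay_rates",
                             config$active_decay_rate)
  node_types <- c(
    stats::setNames(rep("transcript", nrow(expr$values)),
                    rownames(expr$values)),
    stats::setNames(rep("feature", length(feats$feature_id)),
                    feats$feature_id))
  clusters <- functional_clusters(
    detect_clusters(active, min_size = config$min_cluster_size,
                    penalty = config$clusterone_penalty,
                    overlap_threshold = config$overlap_threshold),
    active, node_types, decay_rate = config$active_decay_rate)
  rules <- pfam_filter(rules, config$max_reactions_per_pfam)
  cands <- annotate_features(raw_features, adducts, metabolite_db,
                             ppm = config$ppm)
  nodes <- mass_nodes(raw_features, cands, db = metabolite_db,
                      fallback_adduct = adducts[adducts$name == "[M+H]+", ])
  index <- build_transition_index(rules)
  tol <- transition_tolerance(config$ppm, nodes$mass)
  pairs <- match_mass_pairs(nodes, index, tol)
  gh <- insert_ghosts(pairs, nodes, index, mode = config$ghost_mode,
                      tolerance = tol)
  redges <- attach_enzyme_support(
    gh$pairs, gh$nodes, active, annotations, rules, clusters,
    cluster_restricted = config$cluster_restricted)
  network <- build_network(redges, gh$nodes)
  if (config$rounds > 1 && chem_backend_available()) {
    network <- iterate_prediction(
      network, rules, active, annotations, clusters,
      cluster_restricted = config$cluster_restricted,
      rounds = config$rounds - 1, tolerance = tol)
  }
  roots <- config$roots
  if (is.null(roots)) {
    deg_in <- table(network$edges$product_node)
    deg_out <- table(network$edges$substrate_node)
    roots <- setdiff(names(deg_out), names(deg_in))
    if (length(roots) == 0) roots <- lex_sort(unique(
      network$edges$substrate_node))
  }
  paths <- list()
  pred_rows <- list()
  for (root in lex_sort(roots)) {
    if (!root %in% network$nodes$node_id) next
    pp <- pathway_predictions(network, root)
    for (dirn in c("forward", "reverse")) {
      p <- pp[[dirn]]
      if (is.null(p) || p$length == 0) next
      key <- paste0(root, ":", dirn)
      paths[[key]] <- p
      pred_rows[[key]] <- data.frame(
        root = root, direction = dirn, length = p$length,
        support = sum(p$edges$edge_support),
        nodes = paste(p$nodes, collapse = ";"),
        rules = paste(p$rules, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  predictions <- if (length(pred_rows) > 0) {
    pr <- do.call(rbind, pred_rows)
    pr <- pr[lex_order(-pr$length, -pr$support, pr$nodes), , drop = FALSE]
    rownames(pr) <- NULL
    pr
  } else {
    data.frame(root = character(0), direction = character(0),
               length = integer(0), support = numeric(0),
               nodes = character(0), rules = character(0),
               stringsAsFactors = FALSE)
  }
  list(correlations = edges, networks = networks, clusters = clusters,
       annotations = cands, nodes = gh$nodes, reaction_edges = redges,
       network = network, predictions = predictions, paths = paths)
}

# ---- staged commands over the project store -------------------------------

require_table <- function(store, name, producer) {
  if (!store_has(store, name)) {
    stop2("missing '%s' in the project store; run %s first", name, producer)
  }
}

load_config_inputs <- function(config) {
  list(
    features = read_feature_table(config$features),
    expression = read_expression_matrix(config$expression),
    annotations = utils::read.csv(config$annotations,
                                  stringsAsFactors = FALSE),
    adducts = local({
      ad <- if (is.null(config$adducts)) default_adducts() else
        read_adducts(config$adducts)
      if (identical(config$ionization_mode, "both")) ad else
        ad[ad$mode == config$ionization_mode, , drop = FALSE]
    }))
}

#' Stage command: correlation networks
#'
#' Reads the feature table and expression matrix, aligns samples,
#' optionally MAD-rescales, computes correlations + mutual ranks, and
#' writes `correlations` plus one `MR_weights_DR_<k>` table per decay rate
#' to the project store.
#'
#' @param config a `RunConfig` with `features`, `expression`, `store` set.
#' @return the store handle, invisibly.
#' @export
run_correlate_stage <- function(config) {
  inp <- load_config_inputs(config)
  al <- align_samples(inp$features, inp$expression)
  expr <- al$expr
  feats <- al$features
  if (isTRUE(config$mad_rescaling)) {
    expr <- mad_rescale(expr)
    feats <- mad_rescale(feats)
  }
  edges <- mutual_rank(correlate_pairs(expr, feats,
                                       min_abs_r = config$min_abs_r))
  networks <- decay_weights(edges, decay_rates = config$decay_rates,
                            cutoff = config$weight_cutoff)
  store <- project_store(config$store)
  store_write_table(store, "correlations", edges)
  for (dr in names(networks)) {
    store_write_table(store, paste0("MR_weights_DR_", dr), networks[[dr]])
  }
  store_write_table(store, "node_types", data.frame(
    node_id = c(rownames(expr$values), feats$feature_id),
    type = c(rep("transcript", nrow(expr$values)),
             rep("feature", length(feats$feature_id))),
    stringsAsFactors = FALSE))
  pk_log("correlate: %d edges (|r| >= %g) over %d samples",
         nrow(edges), config$min_abs_r, length(samples(expr)))
  invisible(store)
}

#' Stage command: functional clusters
#'
#' Detects overlapping clusters in each stored decay-rate network and
#' writes one `clusters_DR_<k>` table per rate plus the feature-merged
#' `clusters_merged` table.
#'
#' @param config a `RunConfig`.
#' @return the store handle, invisibly.
#' @export
run_cluster_stage <- function(config) {
  store <- project_store(config$store)
  require_table(store, "correlations", "run_correlate_stage")
  nt <- store_read_table(store, "node_types")
  node_types <- stats::setNames(nt$type, nt$node_id)
  all_fcs <- list()
  for (dr in config$decay_rates) {
    net <- store_read_table(store, paste0("MR_weights_DR_", dr))
    fcs <- functional_clusters(
      detect_clusters(net, min_size = config$min_cluster_size,
                      penalty = config$clusterone_penalty,
                      overlap_threshold = config$overlap_threshold),
      net, node_types, decay_rate = dr)
    store_write_table(store, paste0("clusters_DR_", dr), fcs)
    all_fcs[[as.character(dr)]] <- fcs
    pk_log("cluster: DR=%s -> %d functional cluster(s)", dr, nrow(fcs))
  }
  combined <- do.call(rbind, all_fcs)
  if (nrow(combined) > 0) combined$cluster_id <- seq_len(nrow(combined))
  merged <- merge_shared_feature_clusters(combined, node_types)
  store_write_table(store, "clusters_merged", merged)
  invisible(store)
}

#' Stage command: structure annotation
#'
#' Annotates features with candidate structures by adduct arithmetic and
#' ppm matching; writes `annotations` to the store.
#'
#' @param config a `RunConfig` with `metabolite_db` set.
#' @return the store handle, invisibly.
#' @export
run_annotate_stage <- function(config) {
  if (is.null(config$metabolite_db)) stop2("config$metabolite_db not set")
  inp <- load_config_inputs(config)
  db <- read_metabolite_db(config$metabolite_db)
  cands <- annotate_features(inp$features, inp$adducts, db,
                             ppm = config$ppm)
  store <- project_store(config$store)
  store_write_table(store, "annotations", cands)
  pk_log("annotate: %d candidate(s) for %d feature(s) at %g ppm",
         nrow(cands), length(unique(cands$feature_id)), config$ppm)
  invisible(store)
}

#' Stage command: reaction network and pathway predictions
#'
#' Builds mass-signature nodes, matches rule transitions, inserts ghosts,
#' attaches enzyme support against the active decay-rate network and its
#' clusters, and writes `mass_nodes`, `reaction_edges` and `pathways`.
#'
#' @param config a `RunConfig` with `rules` set.
#' @return the store handle, invisibly.
#' @export
run_predict_stage <- function(config) {
  store <- project_store(config$store)
  require_table(store, "correlations", "run_correlate_stage")
  dr <- config$active_decay_rate
  require_table(store, paste0("MR_weights_DR_", dr), "run_correlate_stage")
  require_table(store, paste0("clusters_DR_", dr), "run_cluster_stage")
  require_table(store, "annotations", "run_annotate_stage")
  inp <- load_config_inputs(config)
  rules <- pfam_filter(
    load_rules(config$rules, tier = config$tier, taxa = config$taxa),
    config$max_reactions_per_pfam)
  db <- if (!is.null(config$metabolite_db))
    read_metabolite_db(config$metabolite_db) else NULL
  active <- store_read_table(store, paste0("MR_weights_DR_", dr))
  clusters <- store_read_table(store, paste0("clusters_DR_", dr))
  cands <- store_read_table(store, "annotations")
  nodes <- mass_nodes(inp$features, cands, db = db,
                      fallback_adduct = inp$adducts[
                        inp$adducts$name == "[M+H]+", ])
  index <- build_transition_index(rules)
  tol <- transition_tolerance(config$ppm, nodes$mass)
  pairs <- match_mass_pairs(nodes, index, tol)
  gh <- insert_ghosts(pairs, nodes, index, mode = config$ghost_mode,
                      tolerance = tol)
  redges <- attach_enzyme_support(
    gh$pairs, gh$nodes, active, inp$annotations, rules, clusters,
    cluster_restricted = config$cluster_restricted)
  network <- build_network(redges, gh$nodes)
  roots <- config$roots %||% lex_sort(unique(redges$substrate_node))
  rows <- list()
  for (root in roots) {
    if (!root %in% network$nodes$node_id) next
    pp <- pathway_predictions(network, root)
    for (dirn in c("forward", "reverse")) {
      p <- pp[[dirn]]
      if (is.null(p) || p$length == 0) next
      rows[[paste0(root, ":", dirn)]] <- data.frame(
        root = root, direction = dirn, length = p$length,
        support = sum(p$edges$edge_support),
        nodes = paste(p$nodes, collapse = ";"),
        rules = paste(p$rules, collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  pathways <- if (length(rows) > 0) {
    pr <- do.call(rbind, rows)
    pr <- pr[lex_order(-pr$length, -pr$support, pr$nodes), , drop = FALSE]
    rownames(pr) <- NULL
    pr
  } else {
    data.frame(root = character(0), direction = character(0),
               length = integer(0), support = numeric(0),
               nodes = character(0), rules = character(0),
               stringsAsFactors = FALSE)
  }
  store_write_table(store, "mass_nodes", gh$nodes)
  store_write_table(store, "reaction_edges", redges)
  store_write_table(store, "pathways", pathways)
  pk_log("predict: %d supported reaction edge(s), %d pathway prediction(s)",
         nrow(redges), nrow(pathways))
  invisible(store)
}

#' Stage command: reaction likelihood scores
#'
#' Scores every reaction edge whose substrate and product nodes both carry
#' structures: atom scores (user CSV, else the built-in heuristic
#' baseline) restricted to the reaction center; writes `likelihoods`.
#' Needs the cheminformatics backend.
#'
#' @param config a `RunConfig`.
#' @return the store handle, invisibly.
#' @export
run_score_stage <- function(config) {
  store <- project_store(config$store)
  require_table(store, "reaction_edges", "run_predict_stage")
  require_table(store, "mass_nodes", "run_predict_stage")
  edges <- store_read_table(store, "reaction_edges")
  nodes <- store_read_table(store, "mass_nodes")
  rules <- pfam_filter(
    load_rules(config$rules, tier = config$tier, taxa = config$taxa),
    config$max_reactions_per_pfam)
  user_scores <- if (!is.null(config$atom_scores))
    read_atom_scores(config$atom_scores) else NULL
  struct_of <- stats::setNames(
    vapply(strsplit(nodes$structures, ";", fixed = TRUE),
           function(v) if (length(v) > 0 && nzchar(v[1])) v[1] else
             NA_character_, character(1)),
    nodes$node_id)
  rows <- list()
  for (k in seq_len(nrow(edges))) {
    s <- struct_of[[edges$substrate_node[k]]]
    p <- struct_of[[edges$product_node[k]]]
    if (is.na(s) || is.na(p)) next
    center <- tryCatch(
      reaction_center(s, p, rules[[edges$rule_id[k]]]),
      error = function(e) NULL)
    if (is.null(center)) next
    scores <- if (!is.null(user_scores)) user_scores[[s]] else
      heuristic_atom_scores(s)[[s]]
    if (is.null(scores)) next
    lik <- tryCatch(reaction_likelihood(scores, center),
                    error = function(e) NA_real_)
    rows[[length(rows) + 1]] <- data.frame(
      substrate_node = edges$substrate_node[k],
      product_node = edges$product_node[k], rule_id = edges$rule_id[k],
      substrate_smiles = s, product_smiles = p,
      center = paste(center, collapse = ";"), likelihood = lik,
      stringsAsFactors = FALSE)
  }
  lik <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(substrate_node = character(0), product_node = character(0),
               rule_id = character(0), substrate_smiles = character(0),
               product_smiles = character(0), center = character(0),
               likelihood = numeric(0), stringsAsFactors = FALSE)
  store_write_table(store, "likelihoods", lik)
  pk_log("score: %d edge(s) scored", nrow(lik))
  invisible(store)
}

#' Stage command: report
#'
#' Exports every store table as CSV (Cytoscape-importable edge/node
#' tables), renders a simple SVG per pathway prediction, and writes a run
#' summary with per-stage counts and the parameter echo.
#'
#' @param config a `RunConfig`.
#' @return the summary list, invisibly.
#' @export
run_report_stage <- function(config) {
  store <- project_store(config$store)
  require_table(store, "correlations", "run_correlate_stage")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  tabs <- store_tables(store)
  counts <- list()
  for (name in tabs) {
    df <- store_read_table(store, name)
    utils::write.csv(df, file.path(config$outdir, paste0(name, ".csv")),
                     row.names = FALSE)
    counts[[name]] <- nrow(df)
  }
  if ("pathways" %in% tabs) {
    pw <- store_read_table(store, "pathways")
    for (i in seq_len(min(nrow(pw), 20))) {
      svg_path <- file.path(config$outdir, sprintf("pathway_%02d.svg", i))
      pathway_svg(strsplit(pw$nodes[i], ";")[[1]],
                  strsplit(pw$rules[i], ";")[[1]], svg_path)
    }
  }
  summary <- list(parameters = unclass(config)[
    !vapply(config, is.null, logical(1))], table_rows = counts)
  yaml::write_yaml(summary, file.path(config$outdir, "run_summary.yaml"))
  pk_log("report: %d table(s) exported to %s", length(tabs), config$outdir)
  invisible(summary)
}

# minimal SVG rendering of a linear pathway: boxes joined by labelled arrows
pathway_svg <- function(nodes, rules, path) {
  bw <- 170
  gap <- 70
  width <- length(nodes) * (bw + gap)
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="120">',
    width))
  for (i in seq_along(nodes)) {
    x <- (i - 1) * (bw + gap) + 10
    lines <- c(lines,
               sprintf('<rect x="%d" y="40" width="%d" height="40" fill="none" stroke="black"/>', x, bw),
               sprintf('<text x="%d" y="65" font-size="11" text-anchor="middle">%s</text>',
                       x + bw %/% 2, nodes[i]))
    if (i < length(nodes)) {
      x2 <- x + bw
      lines <- c(lines,
                 sprintf('<line x1="%d" y1="60" x2="%d" y2="60" stroke="black" marker-end="none"/>', x2, x2 + gap - 20),
                 sprintf('<text x="%d" y="35" font-size="10" text-anchor="middle">%s</text>',
                         x2 + (gap - 20) %/% 2, rules[i]),
                 sprintf('<polygon points="%d,55 %d,60 %d,65" fill="black"/>',
                         x2 + gap - 20, x2 + gap - 10, x2 + gap - 20))
    }
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}
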