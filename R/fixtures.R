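# Deterministic synthetic paired-omics generator with a planted pathway.
#
# The generator emulates the statistical structure of a treatment-induced
# biosynthetic response in a paired transcriptomics/metabolomics
# experiment: a latent induction profile (a step response across samples,
# as in a time-resolved elicitor treatment) drives both the pathway
# transcripts and the pathway metabolite abundances, decoy transcripts and
# features vary independently, and feature m/z values derive from the
# planted neutral masses through a chosen adduct. All randomness flows
# from one integer seed; regeneration with the same seed is identical.

MONO_O <- 15.994915    # monoisotopic oxygen (hydroxylation gain)
MONO_H2 <- 2.015650    # two hydrogens (desaturation loss)
MONO_CH2 <- 14.015650  # methylene (O-methylation gain)
PROTON <- 1.007276

# base scaffold: octylbenzene, C14H22
CHAIN_SCAFFOLD <- "CCCCCCCCc1ccccc1"
CHAIN_SCAFFOLD_MASS <- 190.172150704

# planted transformation ladder on the scaffold: terminal hydroxylation,
# then a chain desaturation, then O-methylation, then further chain
# hydroxylations. The first three transitions are pairwise distinct, so a
# 3-step chain is uniquely identifiable from masses alone.
CHAIN_STEPS <- list(
  list(kind = "hydroxylation", smarts = "[CH3:1]>>[CH2:1]O",
       transition = MONO_O, pfam = "PF00067",
       smiles = "OCCCCCCCCc1ccccc1"),
  list(kind = "desaturation", smarts = "[CH2:1][CH2:2]>>[CH1:1]=[CH1:2]",
       transition = -MONO_H2, pfam = "PF00487",
       smiles = "OCC=CCCCCCc1ccccc1"),
  list(kind = "methylation", smarts = "[OX2H:1]>>[O:1]C",
       transition = MONO_CH2, pfam = "PF08242",
       smiles = "COCC=CCCCCCc1ccccc1"),
  list(kind = "hydroxylation", smarts = "[CH2:1]>>[CH1:1]O",
       transition = MONO_O, pfam = "PF01266",
       smiles = "COCC=CCCCC(O)Cc1ccccc1"),
  list(kind = "hydroxylation", smarts = "[CH2:1]>>[CH1:1]O",
       transition = MONO_O, pfam = "PF03055",
       smiles = "COCC=CCCC(O)C(O)Cc1ccccc1"),
  list(kind = "hydroxylation", smarts = "[CH2:1]>>[CH1:1]O",
       transition = MONO_O, pfam = "PF04116",
       smiles = "COCC=CCC(O)C(O)C(O)Cc1ccccc1"))

#' Generate a planted biosynthetic pathway chain
#'
#' A parent scaffold is transformed `n_steps` times into `n_steps + 1`
#' structures, together with matching single-substrate reaction rules
#' (mapped reaction SMARTS, correct mass transitions, one Pfam association
#' per step, strict tier). The default `kind = "mixed"` ladder applies a
#' terminal hydroxylation, a chain desaturation, then an O-methylation
#' (further steps are hydroxylations), so that for up to three steps every
#' step has a distinct mass transition and the planted rule sequence is
#' uniquely identifiable from masses. `kind = "hydroxylation"` instead
#' hydroxylates repeatedly, giving neutral masses spaced uniformly by
#' +15.994915 Da (monoisotopic oxygen).
#'
#' @param n_steps number of reaction steps (1..6).
#' @param seed integer seed (recorded; the chain itself is deterministic).
#' @param kind `"mixed"` (default) or `"hydroxylation"`.
#' @return list with `smiles`, `masses`, `structure_ids`, `rules` (named
#'   list of `ReactionRule`s) and `rule_order`.
#' @export
generate_pathway_chain <- function(n_steps, seed = 1,
                                   kind = c("mixed", "hydroxylation")) {
  kind <- match.arg(kind)
  stopifnot(n_steps >= 1, n_steps <= 6)
  if (kind == "mixed") {
    steps <- CHAIN_STEPS[seq_len(n_steps)]
  } else {
    oh <- c("OCCCCCCCCc1ccccc1", "OCC(O)CCCCCCc1ccccc1",
            "OCC(O)C(O)CCCCCc1ccccc1", "OCC(O)C(O)C(O)CCCCc1ccccc1",
            "OCC(O)C(O)C(O)C(O)CCCc1ccccc1",
            "OCC(O)C(O)C(O)C(O)C(O)CCc1ccccc1")
    pf <- c("PF00067", "PF08392", "PF00487", "PF01266", "PF03055",
            "PF04116")
    steps <- lapply(seq_len(n_steps), function(i) {
      list(kind = "hydroxylation",
           smarts = if (i == 1) "[CH3:1]>>[CH2:1]O" else
             "[CH2:1]>>[CH1:1]O",
           transition = MONO_O, pfam = pf[i], smiles = oh[i])
    })
  }
  smiles <- c(CHAIN_SCAFFOLD, vapply(steps, `[[`, character(1), "smiles"))
  masses <- CHAIN_SCAFFOLD_MASS +
    cumsum(c(0, vapply(steps, `[[`, numeric(1), "transition")))
  ids <- paste0("S", 0:n_steps)
  tab <- data.frame(
    rule_id = sprintf("%s_step%d",
                      vapply(steps, `[[`, character(1), "kind"),
                      seq_len(n_steps)),
    reaction_ids = sprintf("RXN%04d", seq_len(n_steps)),
    smarts = vapply(steps, `[[`, character(1), "smarts"),
    diameter = 2L,
    direction = "both",
    substrate_mass = masses[seq_len(n_steps)],
    product_mass = masses[seq_len(n_steps) + 1],
    pfam_id = vapply(steps, `[[`, character(1), "pfam"),
    ec_number = sprintf("1.14.14.%d", seq_len(n_steps)),
    tier = "strict",
    taxon = "Viridiplantae",
    stringsAsFactors = FALSE)
  rules <- rules_from_table(tab, tier = "strict")
  list(smiles = smiles, masses = masses, structure_ids = ids,
       rules = rules, rule_order = tab$rule_id, seed = seed)
}

#' Generate a paired omics dataset around a planted chain
#'
#' A latent step-response induction profile across samples drives the
#' pathway transcripts (one per reaction step) and the pathway feature
#' abundances; Gaussian noise of standard deviation `noise_sd` (relative
#' to the unit-scale profile) is added on top, and decoy transcripts and
#' features vary independently of the profile. Feature m/z values are the
#' planted neutral masses observed as protonated ions; decoy m/z values
#' are resampled until no decoy-involving pair difference matches a rule
#' transition. Pathway transcripts carry the Pfam of their rule, decoys
#' carry unrelated Pfams.
#'
#' @param chain output of [generate_pathway_chain()].
#' @param n_samples number of samples (>= 6, default 24).
#' @param n_decoy_transcripts,n_decoy_features decoy counts (defaults bring
#'   the toy dataset to 30 transcripts and 20 features).
#' @param noise_sd Gaussian noise standard deviation (default 0.2).
#' @param seed integer seed; same seed, same dataset.
#' @return `ToyDataset`: list with `expression`, `features`, `rules`,
#'   `metabolite_db`, `adducts`, `annotations`, `truth`, `seed`.
#' @export
generate_paired_omics <- function(chain, n_samples = 24,
                                  n_decoy_transcripts = 27,
                                  n_decoy_features = 16,
                                  noise_sd = 0.2, seed = 1) {
  stopifnot(n_samples >= 6)
  set.seed(seed)
  n_steps <- length(chain$rule_order)
  sample_ids <- sprintf("sample%02d", seq_len(n_samples))
  # latent induction: low baseline then induced (step response)
  profile <- rep(c(0.2, 1), c(floor(n_samples / 2),
                              n_samples - floor(n_samples / 2)))

  tx_ids <- sprintf("TX_step%d", seq_len(n_steps))
  tx_path <- t(vapply(seq_len(n_steps), function(i) {
    scale <- stats::runif(1, 40, 120)
    pmax(scale * (profile + stats::rnorm(n_samples, 0, noise_sd)), 0)
  }, numeric(n_samples)))
  dec_tx_ids <- sprintf("TX_dec%02d", seq_len(n_decoy_transcripts))
  tx_dec <- t(vapply(seq_len(n_decoy_transcripts), function(i) {
    base <- stats::runif(1, 5, 80)
    pmax(base * (1 + stats::rnorm(n_samples, 0, 0.5)), 0)
  }, numeric(n_samples)))
  expr_mat <- rbind(tx_path, tx_dec)
  rownames(expr_mat) <- c(tx_ids, dec_tx_ids)
  colnames(expr_mat) <- sample_ids
  expression <- expression_matrix(expr_mat)

  feat_ids <- sprintf("FT_step%d", 0:n_steps)
  ft_path <- t(vapply(seq_len(n_steps + 1), function(i) {
    scale <- stats::runif(1, 1e4, 1e5)
    pmax(scale * (profile + stats::rnorm(n_samples, 0, noise_sd)), 0)
  }, numeric(n_samples)))
  dec_ft_ids <- sprintf("FT_dec%02d", seq_len(n_decoy_features))
  ft_dec <- t(vapply(seq_len(n_decoy_features), function(i) {
    base <- stats::runif(1, 1e3, 5e4)
    pmax(base * (1 + stats::rnorm(n_samples, 0, 0.5)), 0)
  }, numeric(n_samples)))

  transitions <- vapply(chain$rules, `[[`, numeric(1), "mass_transition")
  planted_mz <- chain$masses + PROTON
  # Decoy masses are constrained so the planted truth stays uniquely
  # identifiable: no decoy-involving mass difference may mimic a rule
  # transition or a two-rule ghost bridge (sums, including 0), and no
  # adduct hypothesis of a decoy ion may alias a planted structure mass.
  signed <- unique(c(transitions, -transitions))
  forbidden <- unique(c(signed, as.vector(outer(signed, signed, "+"))))
  all_adducts <- default_adducts()
  decoy_mass_ok <- function(m, accepted) {
    d <- m - c(chain$masses, accepted)
    if (any(abs(outer(c(d, -d), forbidden, "-")) < 0.01)) return(FALSE)
    hyp <- vapply(seq_len(nrow(all_adducts)), function(a)
      neutral_mass(m + PROTON, all_adducts[a, ]), numeric(1))
    !any(abs(outer(hyp[!is.na(hyp)], chain$masses, "-")) < 0.01)
  }
  decoy_masses <- numeric(0)
  for (i in seq_len(n_decoy_features)) {
    repeat {
      m <- stats::runif(1, 150, 600)
      if (decoy_mass_ok(m, decoy_masses)) break
    }
    decoy_masses <- c(decoy_masses, m)
  }
  ab <- rbind(ft_path, ft_dec)
  colnames(ab) <- sample_ids
  features <- feature_table(
    feature_id = c(feat_ids, dec_ft_ids),
    mz = c(planted_mz, decoy_masses + PROTON),
    abundance = ab,
    rt = stats::runif(n_steps + 1 + n_decoy_features, 30, 900))

  metabolite_db <- data.frame(
    structure_id = chain$structure_ids,
    smiles = chain$smiles,
    monoisotopic_mass = chain$masses,
    name = paste0("planted_", chain$structure_ids),
    taxonomy = "Viridiplantae",
    superclass = "synthetic",
    stringsAsFactors = FALSE)

  decoy_pfams <- sprintf("PF9%04d", seq_len(n_decoy_transcripts))
  annotations <- data.frame(
    transcript_id = c(tx_ids, dec_tx_ids),
    pfam_ids = c(vapply(chain$rules[chain$rule_order], function(r)
      paste(unique(r$associations$pfam_id), collapse = ";"), character(1)),
      decoy_pfams),
    category = c(rep("tailoring", n_steps),
                 rep("other", n_decoy_transcripts)),
    stringsAsFactors = FALSE)

  adducts <- default_adducts()
  structure(list(
    expression = expression, features = features, rules = chain$rules,
    metabolite_db = metabolite_db, adducts = adducts,
    annotations = annotations,
    truth = list(structures = chain$structure_ids,
                 smiles = chain$smiles, masses = chain$masses,
                 feature_ids = feat_ids, rules = chain$rule_order,
                 transcripts = tx_ids),
    seed = seed), class = "ToyDataset")
}

#' @export
print.ToyDataset <- function(x, ...) {
  cat(sprintf(
    "ToyDataset (seed %d): %d transcripts x %d samples, %d features, %d-step planted pathway\n",
    x$seed, nrow(x$expression$values), ncol(x$expression$values),
    length(x$features$feature_id), length(x$truth$rules)))
  invisible(x)
}

#' Convenience: default toy dataset
#' @param seed integer seed.
#' @param n_steps planted pathway length (default 3).
#' @param n_samples samples (default 24).
#' @param noise_sd noise level (default 0.2).
#' @return a `ToyDataset`.
#' @export
toy_dataset <- function(seed = 1, n_steps = 3, n_samples = 24,
                        noise_sd = 0.2) {
  generate_paired_omics(generate_pathway_chain(n_steps, seed),
                        n_samples = n_samples, noise_sd = noise_sd,
                        seed = seed)
}

#' Generate synthetic known/random likelihood score sets
#'
#' Emulates the separation between likelihood scores of experimentally
#' characterized enzyme-substrate pairs (high-median Beta distribution)
#' and randomly assembled pairs (low-median), for exercising
#' [compare_score_sets()].
#'
#' @param n scores per set (>= 5).
#' @param seed integer seed.
#' @return list with numeric vectors `known` and `random`.
#' @export
generate_score_sets <- function(n = 50, seed = 1) {
  stopifnot(n >= 5)
  set.seed(seed)
  list(known = stats::rbeta(n, 8, 3), random = stats::rbeta(n, 3, 8))
}

#' Write a toy dataset as a CSV bundle
#'
#' @param toy a `ToyDataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_toy_dataset <- function(toy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(toy$expression, file.path(dir, "expression.csv"))
  write_feature_table(toy$features, file.path(dir, "features.csv"))
  utils::write.csv(toy$metabolite_db, file.path(dir, "metabolites.csv"),
                   row.names = FALSE)
  utils::write.csv(toy$adducts, file.path(dir, "adducts.csv"),
                   row.names = FALSE)
  utils::write.csv(toy$annotations, file.path(dir, "annotations.csv"),
                   row.names = FALSE)
  rule_rows <- do.call(rbind, lapply(toy$rules, function(r) {
    data.frame(rule_id = r$rule_id,
               reaction_ids = paste(r$reaction_ids, collapse = ";"),
               smarts = r$smarts, diameter = r$diameter,
               direction = r$direction, substrate_mass = r$substrate_mass,
               product_mass = r$product_mass,
               mass_transition = r$mass_transition,
               pfam_id = r$associations$pfam_id,
               ec_number = r$associations$ec_number,
               tier = r$associations$tier, taxon = r$associations$taxon,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rule_rows, file.path(dir, "rules.csv"),
                   row.names = FALSE)
  invisible(dir)
}
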