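# Reaction-rule space: loading, tier/taxonomy/Pfam filtering, mass
# transitions, and database-coverage statistics.
#
# A reaction rule is a single-substrate transformation template (reaction
# SMARTS) with a signed mass transition (product mass - substrate mass) and
# tiered enzyme (Pfam/EC) associations. Tier sets are nested:
# strict (experimentally validated) <= medium <= loose.

TIER_LEVELS <- c(strict = 1L, medium = 2L, loose = 3L)

# crude syntactic screen for obviously broken SMARTS; full validation goes
# through the cheminformatics backend when requested
smarts_syntax_ok <- function(s) {
  if (is.na(s) || !nzchar(s)) return(FALSE)
  if (!grepl(">>", s, fixed = TRUE)) return(FALSE)
  chk <- function(x, open, close) {
    chars <- strsplit(x, "")[[1]]
    depth <- cumsum((chars == open) - (chars == close))
    all(depth >= 0) && depth[length(depth)] == 0
  }
  chk(s, "[", "]") && chk(s, "(", ")")
}

has_stereo <- function(s) grepl("[@/\\\\]", s)

reactant_template <- function(s) sub(">>.*$", "", s)

#' Load reaction rules from a long-format association table
#'
#' The input is one row per (rule, enzyme association):
#' `rule_id, reaction_ids, smarts, diameter, direction, substrate_mass,
#' product_mass, pfam_id, ec_number, tier, taxon` (CSV, or a table of the
#' same shape inside a SQLite file; see [store_read_table()]).
#'
#' Filtering on load: associations above the requested tier are removed
#' (tiers are nested, so `tier = "medium"` keeps strict + medium); when
#' `taxa` is given, associations from other taxa are removed
#' (association-level filtering); rules whose SMARTS carries stereo
#' descriptors (`@`, `/`, `\`) or more than one reactant template are
#' excluded; syntactically broken SMARTS skip the rule with a warning
#' rather than aborting the batch. The mass transition is recomputed as
#' `product_mass - substrate_mass` and checked against any supplied
#' `mass_transition` column (1e-6 Da).
#'
#' @param path CSV path, or a SQLite store path together with `table`.
#' @param tier one of `"strict"`, `"medium"`, `"loose"`.
#' @param taxa optional character vector of taxa to keep.
#' @param table table name when `path` is a SQLite file.
#' @param validate_smarts also parse every SMARTS through the
#'   cheminformatics backend (needs RDKit; default FALSE).
#' @return list of `ReactionRule` objects: each a list with `rule_id`,
#'   `reaction_ids`, `smarts`, `diameter`, `direction`, `substrate_mass`,
#'   `product_mass`, `mass_transition`, and `associations` (data.frame
#'   `pfam_id`, `ec_number`, `tier`, `taxon`).
#' @export
load_rules <- function(path, tier = "strict", taxa = NULL, table = "rules",
                       validate_smarts = FALSE) {
  tier <- match.arg(tier, names(TIER_LEVELS))
  if (grepl("\\.(sqlite|db|sqlite3)$", path)) {
    df <- store_read_table(project_store(path), table)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  rules_from_table(df, tier = tier, taxa = taxa,
                   validate_smarts = validate_smarts)
}

#' Build reaction rules from an in-memory association table
#' @param df long-format association data.frame (see [load_rules()]).
#' @inheritParams load_rules
#' @return list of `ReactionRule` objects.
#' @export
rules_from_table <- function(df, tier = "strict", taxa = NULL,
                             validate_smarts = FALSE) {
  tier <- match.arg(tier, names(TIER_LEVELS))
  need <- c("rule_id", "smarts", "substrate_mass", "product_mass",
            "pfam_id", "tier")
  if (!all(need %in% names(df))) {
    stop2("rule table needs columns: %s", paste(need, collapse = ", "))
  }
  if (!"direction" %in% names(df)) df$direction <- "both"
  if (!"diameter" %in% names(df)) df$diameter <- 2L
  if (!"reaction_ids" %in% names(df)) df$reaction_ids <- df$rule_id
  if (!"ec_number" %in% names(df)) df$ec_number <- NA_character_
  if (!"taxon" %in% names(df)) df$taxon <- NA_character_

  df <- df[TIER_LEVELS[df$tier] <= TIER_LEVELS[tier], , drop = FALSE]
  if (!is.null(taxa)) df <- df[df$taxon %in% taxa, , drop = FALSE]
  if (nrow(df) == 0) return(list())

  out <- list()
  skipped <- character(0)
  valid_cache <- NULL
  if (validate_smarts) {
    usm <- unique(df$smarts)
    info <- rxn_smarts_info(usm)
    valid_cache <- stats::setNames(info$valid & info$n_reactants == 1L,
                                   usm)
  }
  for (rid in unique(df$rule_id)) {
    sub <- df[df$rule_id == rid, , drop = FALSE]
    s <- sub$smarts[1]
    if (!smarts_syntax_ok(s) ||
        (validate_smarts && !isTRUE(valid_cache[[s]]))) {
      skipped <- c(skipped, rid)
      next
    }
    react <- reactant_template(s)
    if (has_stereo(s)) next                    # stereo rules filtered
    if (grepl(".", react, fixed = TRUE)) next  # multi-substrate filtered
    transition <- sub$product_mass[1] - sub$substrate_mass[1]
    if ("mass_transition" %in% names(sub) &&
        is.finite(sub$mass_transition[1]) &&
        abs(sub$mass_transition[1] - transition) > 1e-6) {
      stop2("rule %s: stored mass_transition inconsistent with masses", rid)
    }
    out[[rid]] <- structure(list(
      rule_id = rid,
      reaction_ids = unique(unlist(strsplit(as.character(sub$reaction_ids),
                                            ";", fixed = TRUE))),
      smarts = s,
      diameter = as.integer(sub$diameter[1]),
      direction = sub$direction[1],
      substrate_mass = sub$substrate_mass[1],
      product_mass = sub$product_mass[1],
      mass_transition = transition,
      associations = unique(data.frame(
        pfam_id = sub$pfam_id, ec_number = sub$ec_number, tier = sub$tier,
        taxon = sub$taxon, stringsAsFactors = FALSE))
    ), class = "ReactionRule")
  }
  if (length(skipped) > 0) {
    warning(sprintf("skipped %d rule(s) with unparseable SMARTS: %s",
                    length(skipped), paste(skipped, collapse = ", ")),
            call. = FALSE)
  }
  if (length(out) == 0) return(list())
  out[lex_sort(names(out))]
}

#' Drop associations of promiscuous Pfam domains
#'
#' A Pfam linked to many distinct rules is too generic to support a
#' specific reaction; associations whose Pfam is linked to more than
#' `max_reactions_per_pfam` distinct rules are dropped, and rules left
#' with no association are removed. Idempotent.
#'
#' @param rules list of `ReactionRule`s.
#' @param max_reactions_per_pfam cutoff (default 6).
#' @return filtered rule list.
#' @export
pfam_filter <- function(rules, max_reactions_per_pfam = 6) {
  if (length(rules) == 0) return(rules)
  pf <- unlist(lapply(rules, function(r) unique(r$associations$pfam_id)))
  counts <- table(pf)
  generic <- names(counts)[counts > max_reactions_per_pfam]
  out <- lapply(rules, function(r) {
    r$associations <- r$associations[!r$associations$pfam_id %in% generic, ,
                                     drop = FALSE]
    r
  })
  Filter(function(r) nrow(r$associations) > 0, out)
}

#' Build a mass-transition index over reaction rules
#'
#' Each rule is indexed under its signed transition; rules with
#' `direction = "both"` also appear under the negated transition (the
#' reverse reaction). Lookups return all rules whose transition matches a
#' query mass difference within a tolerance.
#'
#' @param rules list of `ReactionRule`s.
#' @return object of class `TransitionIndex`.
#' @export
build_transition_index <- function(rules) {
  if (length(rules) == 0) {
    tab <- data.frame(transition = numeric(0), rule_id = character(0),
                      orientation = character(0), stringsAsFactors = FALSE)
  } else {
    rows <- lapply(rules, function(r) {
      t1 <- data.frame(transition = r$mass_transition, rule_id = r$rule_id,
                       orientation = "forward", stringsAsFactors = FALSE)
      if (identical(r$direction, "both")) {
        rbind(t1, data.frame(transition = -r$mass_transition,
                             rule_id = r$rule_id, orientation = "reverse",
                             stringsAsFactors = FALSE))
      } else if (identical(r$direction, "retro")) {
        t1$orientation <- "reverse"
        t1
      } else t1
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$transition, tab$rule_id), , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(list(table = tab, rules = rules), class = "TransitionIndex")
}

#' @export
print.TransitionIndex <- function(x, ...) {
  cat(sprintf("TransitionIndex: %d entries over %d rules\n",
              nrow(x$table), length(x$rules)))
  invisible(x)
}

#' Look up rules matching a mass difference
#'
#' @param index a `TransitionIndex`.
#' @param delta observed mass difference (Da, signed).
#' @param tolerance absolute tolerance in Da.
#' @return data.frame of matching entries (`transition`, `rule_id`,
#'   `orientation`).
#' @export
transition_lookup <- function(index, delta, tolerance) {
  tab <- index$table
  if (nrow(tab) == 0) return(tab)
  lo <- findInterval(delta - tolerance, tab$transition,
                     left.open = TRUE) + 1L
  hi <- findInterval(delta + tolerance, tab$transition)
  if (hi < lo) return(tab[0, , drop = FALSE])
  out <- tab[lo:hi, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Goodness-of-fit test of database coverage
#'
#' Tests an observed found/missing split of `total` items against the
#' equal-probability null (expected `total / 2` in each cell):
#' `chi2 = (found - E)^2 / E + (missing - E)^2 / E`, 1 degree of freedom.
#' Symmetric in found vs missing.
#'
#' @param found number of items found in the database.
#' @param total total number of items checked.
#' @return list with `chi2`, `df` (= 1), and `p`.
#' @export
coverage_chisq <- function(found, total) {
  if (total <= 0) stop2("total must be positive")
  if (found < 0 || found > total) stop2("found must lie in [0, total]")
  e <- total / 2
  chi2 <- (found - e)^2 / e + ((total - found) - e)^2 / e
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}
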