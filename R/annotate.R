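# Structure annotation of mass features by adduct arithmetic + ppm lookup.
#
# An observed m/z is the signature of a neutral molecule M carried by some
# ion form (adduct): m/z = (multimer * M + mass_shift) / |charge|. Undoing
# each plausible adduct yields candidate neutral masses, which are matched
# against a metabolite structure table within a ppm tolerance.

#' Read an adduct specification table
#'
#' Columns: `name` (e.g. \code{"[M+H]+"}), `mode` (positive/negative),
#' `charge` (signed, nonzero), `multimer` (the n in \[nM+X\], >= 1),
#' `mass_shift` (Da, signed).
#'
#' @param path CSV path; the default is the table shipped with the package
#'   (48 adducts, positive and negative mode).
#' @return data.frame of adduct specs.
#' @export
read_adducts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "adducts.csv", package = "pathomics")
  }
  ad <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "mode", "charge", "multimer", "mass_shift")
  if (!all(need %in% names(ad))) {
    stop2("adduct table needs columns: %s", paste(need, collapse = ", "))
  }
  if (any(ad$charge == 0)) stop2("adduct charge must be nonzero")
  if (any(ad$multimer < 1)) stop2("adduct multimer must be >= 1")
  if (any(sign(ad$charge) != ifelse(ad$mode == "positive", 1, -1))) {
    stop2("adduct charge sign must match ionization mode")
  }
  ad
}

#' Default adduct table
#' @return the 48-adduct table shipped with the package.
#' @export
default_adducts <- function() read_adducts(NULL)

#' Neutral mass implied by an observed m/z under an adduct hypothesis
#'
#' `M = (mz * |charge| - mass_shift) / multimer`. Non-positive results mean
#' the adduct hypothesis is impossible for that ion (returned as NA so the
#' candidate can be discarded).
#'
#' @param mz observed mass-to-charge (Da/e, positive).
#' @param adduct one row of an adduct table (list or single-row data.frame).
#' @return neutral monoisotopic mass in Da, or NA.
#' @export
neutral_mass <- function(mz, adduct) {
  if (any(mz <= 0)) stop2("m/z must be positive")
  m <- (mz * abs(adduct$charge) - adduct$mass_shift) / adduct$multimer
  ifelse(m > 0, m, NA_real_)
}

#' Predicted m/z of a neutral mass under an adduct (inverse of
#' [neutral_mass()])
#' @param m neutral monoisotopic mass (Da).
#' @param adduct adduct spec row.
#' @return predicted m/z.
#' @export
predicted_mz <- function(m, adduct) {
  (adduct$multimer * m + adduct$mass_shift) / abs(adduct$charge)
}

#' Annotate mass features with candidate structures
#'
#' Every feature x adduct combination is converted to a neutral mass and
#' matched against the metabolite table: a record with database mass M_db
#' is a candidate when `|M - M_db| / M_db * 1e6 <= ppm`. One feature may
#' receive many candidates; features with no candidate stay unannotated
#' (and remain eligible as ghost anchors downstream). Manual annotations
#' (feature_id -> structure_id) bypass matching.
#'
#' @param features a `FeatureTable`.
#' @param adducts adduct table (see [read_adducts()]).
#' @param db metabolite table: data.frame with `structure_id`,
#'   `monoisotopic_mass` and optionally `smiles`, `name`, `taxonomy`,
#'   `superclass`.
#' @param ppm mass tolerance in parts per million (default 20).
#' @param manual optional data.frame `feature_id`, `structure_id` of manual
#'   annotations.
#' @return data.frame with `feature_id`, `adduct_name`, `neutral_mass`,
#'   `structure_id`, `ppm_error`.
#' @export
annotate_features <- function(features, adducts, db, ppm = 20,
                              manual = NULL) {
  if (ppm <= 0) stop2("ppm tolerance must be positive")
  if (nrow(db) == 0) stop2("metabolite table is empty")
  ord <- order(db$monoisotopic_mass)
  dbm <- db$monoisotopic_mass[ord]
  dbid <- db$structure_id[ord]
  rows <- list()
  if (nrow(adducts) > 0) {
    for (ai in seq_len(nrow(adducts))) {
      ad <- adducts[ai, ]
      M <- neutral_mass(features$mz, ad)
      for (fi in which(!is.na(M))) {
        lo <- M[fi] / (1 + ppm * 1e-6)
        hi <- M[fi] / (1 - ppm * 1e-6)
        i1 <- findInterval(lo, dbm) + 1L
        i2 <- findInterval(hi, dbm)
        if (i2 < i1) next
        hits <- i1:i2
        rows[[length(rows) + 1]] <- data.frame(
          feature_id = features$feature_id[fi],
          adduct_name = ad$name,
          neutral_mass = M[fi],
          structure_id = dbid[hits],
          ppm_error = (M[fi] - dbm[hits]) / dbm[hits] * 1e6,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.null(manual) && nrow(manual) > 0) {
    mm <- merge(manual, db[, c("structure_id", "monoisotopic_mass")],
                by = "structure_id")
    rows[[length(rows) + 1]] <- data.frame(
      feature_id = mm$feature_id, adduct_name = "manual",
      neutral_mass = mm$monoisotopic_mass, structure_id = mm$structure_id,
      ppm_error = 0, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(feature_id = character(0), adduct_name = character(0),
                      neutral_mass = numeric(0), structure_id = character(0),
                      ppm_error = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[lex_order(out$feature_id, out$adduct_name, out$structure_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a metabolite structure table
#'
#' CSV with at least `structure_id` and `monoisotopic_mass`; `smiles`,
#' `name`, `taxonomy` and `superclass` are carried through when present.
#'
#' @param path CSV path.
#' @return data.frame of metabolite records.
#' @export
read_metabolite_db <- function(path) {
  db <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("structure_id", "monoisotopic_mass") %in% names(db))) {
    stop2("metabolite table needs structure_id and monoisotopic_mass")
  }
  if (any(db$monoisotopic_mass <= 0)) stop2("monoisotopic_mass must be > 0")
  db
}
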