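# Bridge to the bundled cheminformatics helper (inst/python/chemtools.py).
#
# Structure-aware operations (SMILES validation, monoisotopic masses,
# substructure matching, reaction-template application, reaction centers)
# run in one external process per batch, exchanging JSON. Everything that
# only needs mass arithmetic works without this backend.

chem_script <- function() {
  p <- system.file("python", "chemtools.py", package = "pathomics")
  if (!nzchar(p)) stop2("chemtools.py not found in the installed package")
  p
}

chem_python <- function() {
  Sys.getenv("PATHOMICS_PYTHON", unset = Sys.which("python"))
}

#' Is the cheminformatics backend available?
#'
#' Structure-aware operations (rule application, substructure prescreening,
#' reaction centers) need a Python interpreter with RDKit on the PATH
#' (override with the `PATHOMICS_PYTHON` environment variable). Mass-based
#' stages of the workflow never require it.
#'
#' @return `TRUE` if SMILES can be parsed through the backend.
#' @export
chem_backend_available <- function() {
  cached <- .pathomics_env$chem_available
  if (!is.null(cached)) return(cached)
  ok <- tryCatch({
    res <- chem_call(list(op = "validate", smiles = list("C")))
    isTRUE(res$valid[[1]])
  }, error = function(e) FALSE)
  .pathomics_env$chem_available <- ok
  ok
}

.pathomics_env <- new.env(parent = emptyenv())

chem_call <- function(req) {
  infile <- tempfile(fileext = ".json")
  on.exit(unlink(infile), add = TRUE)
  jsonlite::write_json(req, infile, auto_unbox = TRUE, digits = NA,
                       null = "null")
  out <- suppressWarnings(system2(chem_python(), shQuote(chem_script()),
                                  stdin = infile, stdout = TRUE,
                                  stderr = FALSE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L || length(out) == 0L) {
    stop2("cheminformatics backend failed (is RDKit-enabled python on PATH?)")
  }
  res <- jsonlite::fromJSON(paste(out, collapse = ""),
                            simplifyVector = FALSE)
  if (!isTRUE(res$ok)) stop2("cheminformatics backend error: %s",
                             res$error %||% "unknown")
  res
}

#' Validate SMILES and compute monoisotopic masses
#'
#' @param smiles character vector of SMILES strings.
#' @return data.frame with columns `smiles`, `valid`, `canonical`, `mass`
#'   (monoisotopic, Da) and `n_atoms` (heavy atoms).
#' @export
smiles_info <- function(smiles) {
  res <- chem_call(list(op = "validate", smiles = as.list(smiles)))
  data.frame(
    smiles = smiles,
    valid = vapply(res$valid, isTRUE, logical(1)),
    canonical = vapply(res$canonical,
                       function(x) if (is.null(x)) NA_character_ else x,
                       character(1)),
    mass = vapply(res$mass,
                  function(x) if (is.null(x)) NA_real_ else x, numeric(1)),
    n_atoms = vapply(res$n_atoms,
                     function(x) if (is.null(x)) NA_integer_ else
                       as.integer(x), integer(1)),
    stringsAsFactors = FALSE
  )
}

# logical matrix: structures x SMARTS patterns; NA for unparseable entries
smarts_match <- function(smiles, smarts) {
  res <- chem_call(list(op = "match", smiles = as.list(smiles),
                        smarts = as.list(smarts)))
  m <- t(vapply(res$matrix, function(row) {
    vapply(row, function(x) if (is.null(x)) NA else isTRUE(x), logical(1))
  }, logical(length(smarts))))
  if (length(smarts) == 1L) m <- matrix(m, ncol = 1L)
  dimnames(m) <- list(smiles, smarts)
  m
}

# reaction-SMARTS parseability and reactant-template counts
rxn_smarts_info <- function(smarts) {
  res <- chem_call(list(op = "validate_rxn", smarts = as.list(smarts)))
  data.frame(
    smarts = smarts,
    valid = vapply(res$valid, isTRUE, logical(1)),
    n_reactants = vapply(res$n_reactants,
                         function(x) if (is.null(x)) NA_integer_ else
                           as.integer(x), integer(1)),
    stringsAsFactors = FALSE
  )
}
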