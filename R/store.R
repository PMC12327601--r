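# Single-file relational project store.
#
# All intermediate tables (correlations, per-decay-rate weights, clusters,
# annotations, predictions) persist in one SQLite file so stages can be
# re-run independently and results explored with standard SQLite tooling.
# Table I/O goes through a bundled helper over the system Python's stdlib
# sqlite3; numeric columns travel as shortest-round-trip decimal strings,
# so a loaded table reproduces the saved one bit-identically.

STORE_SCHEMA_VERSION <- "1"

store_script <- function() {
  p <- system.file("python", "storebridge.py", package = "pathomics")
  if (!nzchar(p)) stop2("storebridge.py not found in the installed package")
  p
}

store_exec <- function(args, stdout = TRUE) {
  out <- suppressWarnings(system2(chem_python(),
                                  c(shQuote(store_script()),
                                    vapply(args, shQuote, character(1))),
                                  stdout = stdout, stderr = FALSE))
  status <- if (isFALSE(stdout)) out else attr(out, "status") %||% 0L
  if (status != 0L) stop2("project-store backend failed (%s)",
                          paste(args[1:2], collapse = " "))
  invisible(out)
}

#' Open (or create) a project store
#'
#' @param path SQLite file path; created with the current schema version
#'   when absent.
#' @return handle of class `pathomics_store`.
#' @export
project_store <- function(path) {
  existed <- file.exists(path)
  if (!existed) {
    store_exec(c("init", path, STORE_SCHEMA_VERSION))
  } else {
    meta <- jsonlite::fromJSON(paste(store_exec(c("meta", path)),
                                     collapse = ""))
    ver <- meta$schema_version %||% NA_character_
    if (!identical(ver, STORE_SCHEMA_VERSION)) {
      stop2("project store schema mismatch: expected %s, found %s",
            STORE_SCHEMA_VERSION, ver %||% "none")
    }
  }
  structure(list(path = path), class = "pathomics_store")
}

#' @export
print.pathomics_store <- function(x, ...) {
  cat(sprintf("pathomics project store: %s\n  tables: %s\n", x$path,
              paste(store_tables(x), collapse = ", ")))
  invisible(x)
}

#' List tables in a project store
#' @param store a `pathomics_store`.
#' @return character vector of table names.
#' @export
store_tables <- function(store) {
  unlist(jsonlite::fromJSON(paste(store_exec(c("tables", store$path)),
                                  collapse = "")))
}

#' Does the store contain a table?
#' @param store a `pathomics_store`.
#' @param name table name.
#' @return logical.
#' @export
store_has <- function(store, name) name %in% store_tables(store)

#' Write a data.frame to the project store
#' @param store a `pathomics_store`.
#' @param name table name (replaced if present).
#' @param df data.frame of atomic columns.
#' @return the store, invisibly.
#' @export
store_write_table <- function(store, name, df) {
  classes <- vapply(df, function(col) class(col)[1], character(1))
  classes[classes == "double"] <- "numeric"
  csv <- tempfile(fileext = ".csv")
  on.exit(unlink(csv), add = TRUE)
  ser <- df
  for (j in which(classes == "numeric")) ser[[j]] <- fmt_num(df[[j]])
  for (j in which(classes == "logical")) ser[[j]] <- as.integer(df[[j]])
  utils::write.csv(ser, csv, row.names = FALSE, quote = TRUE, na = "NA")
  store_exec(c("write", store$path, name, csv,
               jsonlite::toJSON(as.list(classes), auto_unbox = TRUE)),
             stdout = FALSE)
  invisible(store)
}

#' Read a table from the project store
#' @param store a `pathomics_store`.
#' @param name table name.
#' @return data.frame with the original column classes.
#' @export
store_read_table <- function(store, name) {
  csv <- tempfile(fileext = ".csv")
  on.exit(unlink(csv), add = TRUE)
  classes <- jsonlite::fromJSON(paste(
    store_exec(c("read", store$path, name, csv)), collapse = ""))
  df <- utils::read.csv(csv, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE,
                        na.strings = "NA")
  for (col in names(classes)) {
    df[[col]] <- switch(classes[[col]],
                        numeric = as.numeric(df[[col]]),
                        integer = as.integer(df[[col]]),
                        logical = as.logical(as.integer(df[[col]])),
                        df[[col]])
  }
  df
}

#' Save a set of project tables
#'
#' @param path store file path.
#' @param tables named list of data.frames.
#' @return the store handle, invisibly.
#' @export
save_project <- function(path, tables) {
  store <- project_store(path)
  for (name in names(tables)) store_write_table(store, name, tables[[name]])
  invisible(store)
}

#' Load all tables of a project store
#'
#' @param path store file path (must exist).
#' @param expected optional character vector of stage tables; absent ones
#'   are reported in the `missing` attribute and logged.
#' @return named list of data.frames.
#' @export
load_project <- function(path, expected = NULL) {
  if (!file.exists(path)) stop2("no project store at %s", path)
  store <- project_store(path)
  names_ <- store_tables(store)
  out <- stats::setNames(lapply(names_, function(n)
    store_read_table(store, n)), names_)
  if (!is.null(expected)) {
    missing <- setdiff(expected, names_)
    if (length(missing) > 0) {
      pk_log("project is partial; missing table(s): %s",
             paste(missing, collapse = ", "))
    }
    attr(out, "missing") <- missing
  }
  out
}
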