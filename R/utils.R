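#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shortest decimal representation that round-trips an IEEE double exactly.
fmt_num <- function(x) {
  out <- character(length(x))
  out[is.na(x)] <- "NA"
  idx <- which(!is.na(x))
  for (i in idx) {
    for (d in c(15L, 16L, 17L)) {
      s <- sprintf("%.*g", d, x[i])
      if (as.numeric(s) == x[i]) break
    }
    out[i] <- s
  }
  out
}

pk_log <- function(fmt, ...) {
  message(sprintf(paste0("[pathomics] ", fmt), ...))
}

stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Deterministic lexicographic order, independent of locale.
lex_order <- function(...) do.call(order, c(list(...), list(method = "radix")))

lex_sort <- function(x) sort(x, method = "radix")
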