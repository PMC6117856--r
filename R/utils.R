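`%||%` <- function(a, b) if (is.null(a)) b else a

# payload values travel inside a single TSV field; the separators are reserved
assert_payload_clean <- function(x) {
  if (length(x) == 0) return(invisible(x))
  txt <- c(names(x), as.character(x))
  if (any(grepl("[\t\n;=]", txt)) || any(grepl("[^\x20-\x7e]", txt))) {
    stop("payload keys/values must be printable ASCII without tab, newline, ';' or '='",
         call. = FALSE)
  }
  invisible(x)
}

encode_payload <- function(x) {
  if (length(x) == 0) return("")
  assert_payload_clean(x)
  paste0(names(x), "=", as.character(x), collapse = ";")
}

decode_payload <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character(0))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  eq <- regexpr("=", parts, fixed = TRUE)
  if (any(eq < 1)) stop("malformed payload entry: ", parts[which(eq < 1)[1]], call. = FALSE)
  out <- substring(parts, eq + 1)
  names(out) <- substring(parts, 1, eq - 1)
  out
}

is_count <- function(x, positive = TRUE) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == trunc(x) &&
    (if (positive) x >= 1 else x >= 0)
}

# key=value serialization used for engine state and config blocks
encode_kv <- function(x) {
  paste0(names(x), "=", vapply(x, format_num, ""), collapse = ";")
}

# %.17g round-trips doubles exactly through as.numeric()
format_num <- function(x) {
  if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
}

format_ms <- function(x) sprintf("%.0f", x)
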