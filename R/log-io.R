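LOG_FORMAT_VERSION <- "1"

iso8601_basic <- function(ms) {
  format(as.POSIXct(ms / 1000, origin = "1970-01-01", tz = "UTC"),
         "%Y%m%dT%H%M%SZ")
}

#' Archive filename for a closed session
#'
#' `session_<user_id>_<end time, ISO-8601 basic, UTC>.tsv` — the end time in
#' the filename marks the archive.
#'
#' @param record a closed `session_record`.
#' @return The bare filename.
#' @export
archive_filename <- function(record) {
  if (record$open) stop("record is still open", call. = FALSE)
  sprintf("session_%s_%s.tsv", record$user_id, iso8601_basic(record$end_ms))
}

log_lines <- function(record) {
  hdr <- c(
    format_version = LOG_FORMAT_VERSION,
    session_id = record$session_id,
    user_id = record$user_id,
    trainer_id = record$trainer_id,
    condition = record$condition,
    masked = if (record$masked) "true" else "false",
    start_ms = format_ms(record$start_ms),
    dro_config = encode_kv(unclass(record$dro_config)))
  if (!is.null(record$ncr_config)) {
    nc <- record$ncr_config
    nc$rng_seed <- NULL
    hdr <- c(hdr, ncr_config = encode_kv(nc))
  }
  hdr <- c(hdr, final_state = serialize_dro_state(record$final_state))
  ev <- record$events
  c(paste0("# ", names(hdr), "\t", unname(hdr)),
    paste(vapply(ev$timestamp_ms, format_ms, ""), ev$kind, ev$actor, ev$payload,
          sep = "\t"))
}

#' Write a closed session record to its archive file
#'
#' The dialect is a small versioned TSV: `# key<TAB>value` header lines
#' (session identity, condition, masking flag, engine configuration, final
#' state) followed by one `timestamp_ms<TAB>kind<TAB>actor<TAB>payload` line
#' per event, UTF-8 with LF line endings. Writing is deterministic: the same
#' record always yields byte-identical output at a deterministic path.
#'
#' @param record a closed `session_record`.
#' @param destination directory for the archive.
#' @return The archive path, invisibly usable (returned visibly).
#' @export
write_log <- function(record, destination) {
  stopifnot(inherits(record, "session_record"))
  if (record$open) stop("cannot archive an open session", call. = FALSE)
  path <- file.path(destination, archive_filename(record))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(log_lines(record), con, sep = "\n", useBytes = TRUE)
  path
}

parse_header_kv <- function(line, lineno) {
  body <- sub("^# ", "", line)
  tab <- regexpr("\t", body, fixed = TRUE)
  if (tab < 1) {
    stop(sprintf("line %d: malformed header line: %s", lineno, line), call. = FALSE)
  }
  stats::setNames(substring(body, tab + 1), substring(body, 1, tab - 1))
}

#' Read an archived session log
#'
#' Accepts plain or gzip-compressed files transparently. Validation is
#' strict: missing header keys, a missing terminal `session_end`, and
#' non-monotone timestamps are hard errors naming the offending line. Events
#' of unknown kind are preserved (forward compatibility) and listed in the
#' returned record's `warnings` field.
#'
#' @param path path to a `.tsv` (or `.tsv.gz`) session log.
#' @return A closed `session_record`.
#' @export
read_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  is_hdr <- grepl("^# ", lines)
  if (any(is_hdr & cumsum(!is_hdr) > 0)) {
    stop(sprintf("line %d: header line after start of event body",
                 which(is_hdr & cumsum(!is_hdr) > 0)[1]), call. = FALSE)
  }
  hdr <- character(0)
  for (i in which(is_hdr)) hdr <- c(hdr, parse_header_kv(lines[i], i))
  need <- c("format_version", "session_id", "user_id", "trainer_id",
            "condition", "masked", "start_ms", "dro_config", "final_state")
  missing <- setdiff(need, names(hdr))
  if (length(missing)) {
    stop("missing header keys: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!hdr[["condition"]] %in% c("DRO", "NCR")) {
    stop("unknown condition: ", hdr[["condition"]], call. = FALSE)
  }

  body_idx <- which(!is_hdr & nzchar(lines))
  if (!length(body_idx)) stop("log contains no events", call. = FALSE)
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  # strsplit drops a trailing empty field; an empty payload is legal
  trail <- endsWith(lines[body_idx], "\t")
  fields <- mapply(function(f, tr) if (length(f) == 3 && tr) c(f, "") else f,
                   fields, trail, SIMPLIFY = FALSE)
  nf <- lengths(fields)
  if (any(nf != 4)) {
    bad <- body_idx[which(nf != 4)[1]]
    stop(sprintf("line %d: expected 4 tab-separated fields", bad), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  ts <- suppressWarnings(as.numeric(m[, 1]))
  if (anyNA(ts)) {
    stop(sprintf("line %d: non-numeric timestamp", body_idx[which(is.na(ts))[1]]),
         call. = FALSE)
  }
  drop <- diff(ts) < 0
  if (any(drop)) {
    stop(sprintf("line %d: timestamp decreases", body_idx[which(drop)[1] + 1]),
         call. = FALSE)
  }
  events <- data.frame(timestamp_ms = ts, kind = m[, 2], actor = m[, 3],
                       payload = m[, 4], stringsAsFactors = FALSE)
  if (events$kind[1] != "session_start") {
    stop(sprintf("line %d: first event must be session_start", body_idx[1]),
         call. = FALSE)
  }
  ends <- which(events$kind == "session_end")
  if (length(ends) != 1 || ends != nrow(events)) {
    stop("unterminated session: exactly one terminal session_end required",
         call. = FALSE)
  }
  unknown <- setdiff(unique(events$kind), EVENT_KINDS)
  warnings <- if (length(unknown)) {
    sprintf("unknown event kind preserved: %s", unknown)
  } else character(0)

  dro_cfg <- decode_payload(hdr[["dro_config"]])
  dro_cfg <- do.call(dro_config, as.list(stats::setNames(as.numeric(dro_cfg),
                                                         names(dro_cfg))))
  ncr_cfg <- NULL
  if ("ncr_config" %in% names(hdr)) {
    kv <- decode_payload(hdr[["ncr_config"]])
    ncr_cfg <- ncr_config(
      initial_mean_interval = as.numeric(kv[["initial_mean_interval"]]),
      points_per_reward_multiplier = as.numeric(kv[["points_per_reward_multiplier"]]))
  }
  final_state <- parse_dro_state(hdr[["final_state"]])
  end_reason <- decode_payload(events$payload[nrow(events)])[["reason"]]

  structure(
    list(session_id = hdr[["session_id"]],
         user_id = hdr[["user_id"]], trainer_id = hdr[["trainer_id"]],
         condition = hdr[["condition"]],
         masked = identical(hdr[["masked"]], "true"),
         start_ms = as.numeric(hdr[["start_ms"]]),
         end_ms = ts[length(ts)],
         end_reason = end_reason, open = FALSE,
         dro_config = dro_cfg, ncr_config = ncr_cfg,
         state = final_state, final_state = final_state,
         last_ms = ts[length(ts)],
         last_trainer_ms = NA_real_,
         events = events,
         warnings = warnings),
    class = "session_record")
}
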