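# Structured event log. Automatic steps that fall back to defaults (low NCC,
# missing base, retraction, clipped boxes) record an event here so a
# proofreading pass can target exactly the uncertain decisions.

.filo_log <- new.env(parent = emptyenv())
.filo_log$events <- list()

log_event <- function(.type, ...) {
  ev <- c(list(type = .type), list(...))
  .filo_log$events[[length(.filo_log$events) + 1L]] <- ev
  invisible(ev)
}

#' Access the structured event log
#'
#' Automatic workflow steps log every fallback and every retraction decision
#' (`type` one of `"low_ncc_root"`, `"low_ncc_base"`, `"retraction"`,
#' `"mismatch"`, `"short_filopodium"`, `"base_fallback"`, `"box_clipped"`,
#' `"root_in_background"`, ...). `clear_log()` empties it; `write_log()`
#' exports it as JSON lines.
#'
#' @param path output file for `write_log` (JSONL, one event per line).
#' @return `get_log()`: list of events in order of occurrence.
#' @export
get_log <- function() .filo_log$events

#' @rdname get_log
#' @export
clear_log <- function() {
  .filo_log$events <- list()
  invisible(NULL)
}

#' @rdname get_log
#' @export
write_log <- function(path) {
  lines <- vapply(.filo_log$events, function(ev)
    jsonlite::toJSON(ev, auto_unbox = TRUE, digits = NA), character(1))
  writeLines(lines, path)
  invisible(path)
}

log_types <- function() vapply(get_log(), function(e) e$type, character(1))
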