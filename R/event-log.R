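#' Event logs
#'
#' An event log is the raw-data format of the simulator and of the analysis
#' pipeline: one time-ordered stream of events for one subject and one task
#' block. It is a data frame with columns `t` (ms from block start), `kind`,
#' `epoch_id`, `threat_level`, `token_index`, `side`, plus the attributes
#' `subject_id`, `block_id`, `task` ("task1" or "task2") and `config_hash`.
#'
#' Event kinds: `epoch_start`, `token_on`, `token_off`, `leave_safe`,
#' `token_collected`, `enter_safe`, `predator_wake`, `caught`, `key_up`,
#' `expose_success`, `expose_fail`, `epoch_end`.
#'
#' @param events Data frame of events.
#' @param subject_id,block_id Identifiers.
#' @param task "task1" or "task2".
#' @param config The `task_config` the block was generated or recorded under.
#' @return An object of class `event_log` (a data frame).
#' @export
event_log <- function(events, subject_id, block_id, task, config) {
  stopifnot(task %in% c("task1", "task2"))
  cols <- c("t", "kind", "epoch_id", "threat_level", "token_index", "side")
  missing_cols <- setdiff(cols, names(events))
  for (mc in missing_cols) events[[mc]] <- NA
  events <- events[, cols]
  rownames(events) <- NULL
  log <- structure(events,
                   subject_id = subject_id,
                   block_id = block_id,
                   task = task,
                   config_hash = config_hash(config),
                   class = c("event_log", "data.frame"))
  log
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> subject %s, block %s, %s: %d events, %d epochs\n",
              attr(x, "subject_id"), attr(x, "block_id"), attr(x, "task"),
              nrow(x), length(unique(x$epoch_id))))
  print(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat(sprintf("  ... %d more events\n", nrow(x) - 8))
  invisible(x)
}

#' Stable hash of a task configuration
#'
#' MD5 of the canonical JSON serialization; used to stamp event logs and run
#' manifests so that analyses can verify they were produced under the same
#' task constants.
#'
#' @param config A `task_config` (or any list of plain values).
#' @return A 32-character hexadecimal string.
#' @export
config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), digits = NA, auto_unbox = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(json, tf)
  unname(tools::md5sum(tf))
}

#' Write and read event logs as JSON lines
#'
#' One JSON object per event per line; subject, block, task and config hash
#' are written to a sidecar manifest `<path>.manifest.json`.
#'
#' @param log An `event_log`.
#' @param path Output path for the JSONL stream.
#' @return `write_event_log` returns `path` invisibly; `read_event_log`
#'   returns the reconstructed `event_log`.
#' @export
write_event_log <- function(log, path) {
  df <- as.data.frame(log)
  con <- file(path, open = "w")
  jsonlite::stream_out(df, con, verbose = FALSE, digits = NA, na = "null")
  close(con)
  manifest <- list(subject_id = attr(log, "subject_id"),
                   block_id = attr(log, "block_id"),
                   task = attr(log, "task"),
                   config_hash = attr(log, "config_hash"),
                   n_events = nrow(df))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  con <- file(path, open = "r")
  events <- jsonlite::stream_in(con, verbose = FALSE)
  close(con)
  cols <- c("t", "kind", "epoch_id", "threat_level", "token_index", "side")
  for (mc in setdiff(cols, names(events))) events[[mc]] <- NA
  events <- events[, cols]
  man <- jsonlite::read_json(paste0(path, ".manifest.json"),
                             simplifyVector = TRUE)
  structure(events,
            subject_id = man$subject_id, block_id = man$block_id,
            task = man$task, config_hash = man$config_hash,
            class = c("event_log", "data.frame"))
}

log_task <- function(log) attr(log, "task")
log_subject <- function(log) attr(log, "subject_id")

assert_task <- function(log, task) {
  if (!inherits(log, "event_log")) stop("expected an event_log", call. = FALSE)
  if (!identical(log_task(log), task)) {
    stop(sprintf("expected a %s log, got %s", task, log_task(log)),
         call. = FALSE)
  }
  invisible(log)
}

# split an event log into per-epoch data frames, dropping malformed epochs
# (no epoch_end) with a warning
epoch_split <- function(log) {
  df <- as.data.frame(log)
  sp <- split(df, df$epoch_id)
  ok <- vapply(sp, function(e) any(e$kind == "epoch_end"), logical(1))
  if (any(!ok)) {
    warning(sprintf("skipping %d malformed epoch(s) without epoch_end",
                    sum(!ok)), call. = FALSE)
  }
  sp[ok]
}
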