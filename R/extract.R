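#' Reconstruct approach decisions from a Task-1 event log
#'
#' Each uncaught epoch yields six binary records, one per possible token:
#' record `i` scores 1 if at least `i` tokens were collected in the epoch and
#' 0 otherwise, with potential loss `i - 1` (the tokens at stake when token
#' `i` is considered). Epochs on which the player was caught cannot be
#' reconstructed and yield no records. Epochs without an `epoch_end` event
#' are skipped with a warning.
#'
#' @param log An [event_log()] with `task = "task1"`.
#' @return Data frame with columns `subject_id`, `block_id`, `epoch_id`,
#'   `threat_level`, `token_index` (1-6), `potential_loss` (0-5),
#'   `approached` (0/1).
#' @export
reconstruct_decisions <- function(log) {
  assert_task(log, "task1")
  epochs <- epoch_split(log)
  n_tok <- 6L
  out <- lapply(epochs, function(e) {
    if (any(e$kind == "caught")) return(NULL)
    n_coll <- sum(e$kind == "token_collected")
    data.frame(subject_id = attr(log, "subject_id"),
               block_id = attr(log, "block_id"),
               epoch_id = e$epoch_id[1],
               threat_level = e$threat_level[1],
               token_index = seq_len(n_tok),
               potential_loss = seq_len(n_tok) - 1L,
               approached = as.integer(seq_len(n_tok) <= n_coll),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(subject_id = character(0), block_id = integer(0),
                      epoch_id = integer(0), threat_level = character(0),
                      token_index = integer(0), potential_loss = integer(0),
                      approached = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Extract approach and return latencies from a Task-1 event log
#'
#' One record per collected token with index 1-5 (the sixth token is excluded
#' from all latency analysis). Approach latency runs from token onset to the
#' key press leaving the safe place; return latency from token collection to
#' re-entering the safe place and is undefined when the excursion ended in a
#' catch. Latencies outside the configured response windows (open intervals)
#' are set to `NA` but the record is retained with an exclusion flag for
#' audit.
#'
#' @param log An [event_log()] with `task = "task1"`.
#' @param config The [task_config()] providing the response windows.
#' @return Data frame with columns `subject_id`, `block_id`, `epoch_id`,
#'   `threat_level`, `potential_loss` (0-4), `approach_latency_ms`,
#'   `return_latency_ms`, `caught`, `approach_excluded`, `return_excluded`.
#' @export
extract_latencies <- function(log, config) {
  assert_task(log, "task1")
  stopifnot(inherits(config, "task_config"))
  aw <- config$approach_window
  rw <- config$return_window
  epochs <- epoch_split(log)
  out <- lapply(epochs, function(e) {
    coll <- e[e$kind == "token_collected", , drop = FALSE]
    if (nrow(coll) == 0) return(NULL)
    recs <- lapply(seq_len(nrow(coll)), function(j) {
      idx <- coll$token_index[j]
      if (idx > 5L) return(NULL)  # sixth token excluded from RT analysis
      t_on <- e$t[e$kind == "token_on" & e$token_index == idx]
      t_leave <- e$t[e$kind == "leave_safe" & e$token_index == idx]
      if (length(t_on) != 1 || length(t_leave) != 1) {
        stop("orphan collection event: no matching token_on/leave_safe",
             call. = FALSE)
      }
      al <- t_leave - t_on
      # excursion outcome: next enter_safe or caught after this collection
      t_enter <- e$t[e$kind == "enter_safe" & e$token_index == idx]
      caught_here <- any(e$kind == "caught" & e$token_index == idx)
      rl <- if (length(t_enter) == 1) t_enter - coll$t[j] else NA_real_
      al_ok <- is.finite(al) && al > aw[1] && al < aw[2]
      rl_ok <- is.finite(rl) && rl > rw[1] && rl < rw[2]
      data.frame(subject_id = attr(log, "subject_id"),
                 block_id = attr(log, "block_id"),
                 epoch_id = e$epoch_id[1],
                 threat_level = e$threat_level[1],
                 potential_loss = j - 1L,
                 approach_latency_ms = if (al_ok) al else NA_real_,
                 return_latency_ms = if (rl_ok) rl else NA_real_,
                 caught = caught_here,
                 approach_excluded = !al_ok,
                 return_excluded = !rl_ok && !caught_here,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(subject_id = character(0), block_id = integer(0),
                      epoch_id = integer(0), threat_level = character(0),
                      potential_loss = integer(0),
                      approach_latency_ms = numeric(0),
                      return_latency_ms = numeric(0), caught = logical(0),
                      approach_excluded = logical(0),
                      return_excluded = logical(0))
  }
  rownames(out) <- NULL
  out
}

#' True catch rates per threat level
#'
#' The realized per-excursion catch probability: an excursion is a
#' `leave_safe` to (`enter_safe` or `caught`) span; the rate is
#' `100 * catches / excursions` for each threat level, `NA` where the level
#' had no excursions.
#'
#' @param log An [event_log()] with `task = "task1"`.
#' @return Data frame with columns `subject_id`, `threat_level`,
#'   `excursions`, `catches`, `rate` (percent).
#' @export
true_catch_rates <- function(log) {
  assert_task(log, "task1")
  df <- as.data.frame(log)
  levels <- threat_levels()
  exc <- vapply(levels, function(l) {
    sum(df$kind == "leave_safe" & df$threat_level == l)
  }, numeric(1))
  cat_ <- vapply(levels, function(l) {
    sum(df$kind == "caught" & df$threat_level == l)
  }, numeric(1))
  data.frame(subject_id = attr(log, "subject_id"),
             threat_level = levels,
             excursions = exc,
             catches = cat_,
             rate = ifelse(exc > 0, 100 * cat_ / exc, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Count approach-and-survive trials
#'
#' The performance measure used for control quality control: the number of
#' tokens the player approached and collected on excursions that did not end
#' in a catch.
#'
#' @param logs A single [event_log()] or a list of Task-1 logs for one
#'   subject.
#' @return Integer count.
#' @export
approach_survival_count <- function(logs) {
  if (inherits(logs, "event_log")) logs <- list(logs)
  sum(vapply(logs, function(log) {
    assert_task(log, "task1")
    df <- as.data.frame(log)
    per_epoch <- split(df, df$epoch_id)
    sum(vapply(per_epoch, function(e) {
      coll <- e$token_index[e$kind == "token_collected"]
      caught_idx <- e$token_index[e$kind == "caught"]
      # the collection whose excursion ended in the catch did not survive
      length(coll) - length(caught_idx)
    }, numeric(1)))
  }, numeric(1)))
}

#' Leave-one-out performance exclusion of control participants
#'
#' A control subject is excluded when its approach-and-survive count falls
#' more than `sd_threshold` standard deviations below the mean of the
#' remaining controls (leave-one-out mean and SD). Applied iteratively to a
#' fixed point, worst subject first; exclusion requires a strictly positive
#' leave-one-out SD.
#'
#' @param counts Named numeric vector of approach-and-survive counts, one per
#'   control subject (>= 3 subjects).
#' @param sd_threshold Exclusion threshold in SD units (default 4).
#' @return List with `kept` and `excluded` character vectors and the final
#'   `z` scores (leave-one-out) of all subjects.
#' @examples
#' performance_qc(c(a = 100, b = 102, c = 98, d = 5))
#' @export
performance_qc <- function(counts, sd_threshold = 4) {
  if (is.null(names(counts))) names(counts) <- seq_along(counts)
  if (length(counts) < 3) stop("need >= 3 control subjects", call. = FALSE)
  kept <- names(counts)
  excluded <- character(0)
  repeat {
    x <- counts[kept]
    z <- vapply(seq_along(x), function(i) {
      m <- mean(x[-i]); s <- stats::sd(x[-i])
      if (!is.finite(s) || s <= 0) return(0)
      (x[i] - m) / s
    }, numeric(1))
    names(z) <- names(x)
    worst <- which.min(z)
    if (z[worst] < -sd_threshold) {
      excluded <- c(excluded, names(x)[worst])
      kept <- setdiff(kept, names(x)[worst])
      if (length(kept) == 0) {
        stop("performance QC excluded every control subject", call. = FALSE)
      }
    } else {
      return(list(kept = kept, excluded = excluded, z = z))
    }
  }
}

#' Per-subject condition means of approach proportion
#'
#' Averages the reconstructed decisions within each of the 18 design cells
#' (3 threat levels x 6 potential-loss levels) per subject. Cells without
#' observations get `NA` and are flagged.
#'
#' @param decisions Decision table from [reconstruct_decisions()] (rows from
#'   several subjects/blocks may be concatenated).
#' @return Data frame with columns `subject_id`, `threat_level`,
#'   `potential_loss`, `approach_proportion`, `n_epochs`, `empty`.
#' @export
condition_means <- function(decisions) {
  grid <- expand.grid(subject_id = unique(decisions$subject_id),
                      threat_level = threat_levels(),
                      potential_loss = 0:5,
                      stringsAsFactors = FALSE)
  agg <- stats::aggregate(approached ~ subject_id + threat_level +
                            potential_loss,
                          data = decisions, FUN = mean)
  cnt <- stats::aggregate(approached ~ subject_id + threat_level +
                            potential_loss,
                          data = decisions, FUN = length)
  names(agg)[4] <- "approach_proportion"
  names(cnt)[4] <- "n_epochs"
  out <- merge(merge(grid, agg, all.x = TRUE), cnt, all.x = TRUE)
  out$n_epochs[is.na(out$n_epochs)] <- 0L
  out$empty <- out$n_epochs == 0L
  out <- out[order(out$subject_id, match(out$threat_level, threat_levels()),
                   out$potential_loss), ]
  rownames(out) <- NULL
  out
}
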