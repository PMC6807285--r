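#' Simulate a block of the safe predator exposure task
#'
#' Epochs reuse the Task-1 token timing (six scheduled token cycles per
#' epoch, exponential availability and offset exponential waits) but the
#' player stays in the safe place and instead tries to "expose" the awake
#' predator with the up key. Each attempt succeeds independently with the
#' epoch's threat-level wake-up probability; after
#' `config$exposure_attempts_max` attempts (or a success) the key is disabled
#' for the rest of the epoch. Intended press times are generated from the
#' agent's two-component process: with probability `w` uniform over the epoch
#' timeline, otherwise exGauss-delayed reactions to a token onset; intents
#' beyond the attempt cap are dropped without an event, matching the disabled
#' key.
#'
#' @param config A [task_config()].
#' @param epolicy An [exposure_policy()].
#' @param seed Optional integer seed.
#' @param subject_id,block_id Identifiers stamped on the log.
#' @return An [event_log()] with `task = "task2"`; each attempt appears as a
#'   `key_up` event immediately followed by `expose_success` or
#'   `expose_fail`.
#' @examples
#' log <- simulate_task2_block(task_config(), exposure_policy(), seed = 1)
#' mean(log$kind == "expose_success")
#' @export
simulate_task2_block <- function(config, epolicy, seed = NULL,
                                 subject_id = "agent", block_id = 1L) {
  stopifnot(inherits(config, "task_config"))
  if (!inherits(epolicy, "exposure_policy")) {
    stop("`epolicy` must be an exposure_policy()", call. = FALSE)
  }
  with_seed(seed, {
    threats <- balanced_threats(config$exposure_epochs_per_block)
    rate <- 1 / config$availability_mean
    t0 <- 0
    parts <- vector("list", length(threats))
    for (e in seq_along(threats)) {
      threat <- threats[e]
      n_tok <- config$tokens_per_epoch
      waits <- stats::rexp(n_tok, rate) + config$wait_offset
      avails <- stats::rexp(n_tok, rate)
      t_on <- t0 + cumsum(waits + c(0, avails[-n_tok]))
      t_off <- t_on + avails
      dur <- t_off[n_tok] - t0

      n_intent <- stats::rpois(1, epolicy$presses_per_epoch_mean)
      press_t <- numeric(0)
      if (n_intent > 0) {
        from_null <- stats::runif(n_intent) < epolicy$w
        p_null <- stats::runif(sum(from_null), t0, t0 + dur)
        n_exg <- sum(!from_null)
        p_exg <- numeric(0)
        if (n_exg > 0) {
          tok <- sample.int(n_tok, n_exg, replace = TRUE)
          p_exg <- t_on[tok] + rexgauss(n_exg, epolicy$mu, epolicy$sigma,
                                        epolicy$lam)
          p_exg <- p_exg[p_exg <= t0 + dur]  # epoch over; intent never realized
        }
        press_t <- sort(c(p_null, p_exg))
      }

      ev <- data.frame(t = c(t0, t_on, t_off),
                       kind = c("epoch_start", rep("token_on", n_tok),
                                rep("token_off", n_tok)),
                       token_index = c(NA, seq_len(n_tok), seq_len(n_tok)),
                       stringsAsFactors = FALSE)
      attempts <- 0L
      for (tp in press_t) {
        if (attempts >= config$exposure_attempts_max) break  # key disabled
        attempts <- attempts + 1L
        success <- stats::runif(1) < config$hazards[[threat]]
        ev <- rbind(ev, data.frame(
          t = c(tp, tp),
          kind = c("key_up", if (success) "expose_success" else "expose_fail"),
          token_index = NA_integer_, stringsAsFactors = FALSE))
        if (success) break  # predator exposed; key disabled
      }
      ev <- rbind(ev, data.frame(t = t0 + dur, kind = "epoch_end",
                                 token_index = NA_integer_,
                                 stringsAsFactors = FALSE))
      ev$epoch_id <- e
      ev$threat_level <- threat
      ev$side <- NA_character_
      parts[[e]] <- ev[order(ev$t, seq_len(nrow(ev))), ]
      t0 <- t0 + dur
    }
    event_log(do.call(rbind, parts), subject_id, block_id, "task2", config)
  })
}
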