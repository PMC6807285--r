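#' Simulate one epoch of the approach-avoidance conflict task
#'
#' One epoch schedules `tokens_per_epoch` token cycles. Before each token a
#' waiting interval is drawn from an exponential distribution (mean
#' `availability_mean`) plus `wait_offset`; the token then stays available for
#' an exponential interval (mean `availability_mean`). The agent forages
#' sequentially: it keeps collecting tokens until it first declines, then
#' sits out the rest of the epoch. The conditional continue probabilities
#' are chosen so that the marginal probability of going for token `i` is
#' logistic-linear in the threat code and the potential loss `i - 1` — the
#' same quantity the decision reconstruction analyzes. A realized approach
#' always collects: the approach latency is Gaussian truncated to the
#' token's availability window, collection is instantaneous upon leaving
#' the safe place, and the agent is then exposed to the predator for its
#' return latency, discretized into `step_ms` steps each carrying the
#' threat level's activation hazard. A catch removes all held tokens and
#' disables collection for the rest of the epoch; remaining tokens still
#' appear and expire.
#'
#' Uses the current RNG stream unless `seed` is given.
#'
#' @param config A [task_config()].
#' @param policy An [approach_policy()].
#' @param threat Threat level: "low", "med" or "high".
#' @param epoch_id Integer epoch identifier stamped on the events.
#' @param t0 Block-clock time (ms) at which the epoch starts.
#' @param seed Optional integer seed.
#' @return A data frame of events (see [event_log()] for the kinds).
#' @export
simulate_task1_epoch <- function(config, policy, threat, epoch_id = 1L,
                                 t0 = 0, seed = NULL) {
  stopifnot(inherits(config, "task_config"), inherits(policy, "approach_policy"))
  if (any(!is.finite(unlist(unclass(policy))))) {
    stop("approach policy parameters must be finite", call. = FALSE)
  }
  threat <- match.arg(threat, threat_levels())
  with_seed(seed, {
    th <- threat_code(threat)
    hazard <- config$hazards[[threat]]
    rate <- 1 / config$availability_mean
    ev <- vector("list", 6L * config$tokens_per_epoch + 4L)
    n_ev <- 0L
    emit <- function(t, kind, token_index = NA_integer_, side = NA_character_) {
      n_ev <<- n_ev + 1L
      ev[[n_ev]] <<- list(t = t, kind = kind, token_index = token_index,
                          side = side)
    }
    t <- t0
    emit(t, "epoch_start")
    collected <- 0L
    caught <- FALSE
    stopped <- FALSE
    cum_p <- 1
    for (i in seq_len(config$tokens_per_epoch)) {
      wait <- stats::rexp(1, rate) + config$wait_offset
      t_on <- t + wait
      avail <- stats::rexp(1, rate)
      side <- sample(c("left", "right"), 1L)
      emit(t_on, "token_on", i, side)
      cycle_end <- t_on + avail
      approached <- FALSE
      if (!caught && !stopped) {
        # marginal P(collect >= i) is logistic-linear in threat and loss;
        # realized sequentially through the conditional continue probability
        p_i <- stats::plogis(policy$approach_intercept +
                               policy$approach_coef_threat * th +
                               policy$approach_coef_loss * (i - 1L))
        p_cond <- min(1, p_i / cum_p)
        if (stats::runif(1) < p_cond) {
          cum_p <- cum_p * p_cond
          # reaction happens while the token is on screen: latency is a
          # Gaussian truncated to [1 ms, availability)
          al <- rnorm_trunc(policy$al_base + policy$al_coef_threat * th +
                              policy$al_coef_loss * (i - 1L),
                            policy$latency_noise_sd,
                            lo = 1, hi = max(avail - 1, 2))
          approached <- TRUE
          t_press <- t_on + al
          emit(t_press, "leave_safe", i, side)
          emit(t_press, "token_collected", i, side)
          collected <- collected + 1L
          rl <- max(1, stats::rnorm(1, policy$rl_base +
                                      policy$rl_coef_threat * th +
                                      policy$rl_coef_loss * (collected - 1L),
                                    policy$latency_noise_sd))
          n_steps <- floor(rl / config$step_ms)
          wake_step <- 0L
          if (n_steps >= 1L) {
            hit <- stats::runif(n_steps) < hazard
            if (any(hit)) wake_step <- which(hit)[1L]
          }
          if (wake_step > 0L) {
            t_caught <- t_press + wake_step * config$step_ms
            emit(t_caught, "predator_wake", i)
            emit(t_caught, "caught", i)
            caught <- TRUE
            cycle_end <- t_caught
          } else {
            t_enter <- t_press + rl
            emit(t_enter, "enter_safe", i, side)
            cycle_end <- t_enter
          }
        } else {
          stopped <- TRUE  # foraging ends for this epoch
        }
      }
      if (!approached) emit(t_on + avail, "token_off", i, side)
      t <- cycle_end
    }
    emit(t, "epoch_end")
    out <- data.frame(
      t = vapply(ev[seq_len(n_ev)], `[[`, numeric(1), "t"),
      kind = vapply(ev[seq_len(n_ev)], `[[`, character(1), "kind"),
      epoch_id = epoch_id,
      threat_level = threat,
      token_index = vapply(ev[seq_len(n_ev)], `[[`, integer(1), "token_index"),
      side = vapply(ev[seq_len(n_ev)], `[[`, character(1), "side"),
      stringsAsFactors = FALSE
    )
    out[order(out$t, seq_len(nrow(out))), , drop = FALSE]
  })
}

# Gaussian truncated to [lo, hi] by inverse-CDF sampling
rnorm_trunc <- function(mean, sd, lo, hi) {
  if (sd <= 0) return(min(max(mean, lo), hi))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi <= plo) return(min(max(mean, lo), hi))
  stats::qnorm(stats::runif(1, plo, phi), mean, sd)
}

# balanced (or near-balanced, with warning) shuffled threat assignment
balanced_threats <- function(n_epochs) {
  n_each <- n_epochs %/% 3L
  rem <- n_epochs %% 3L
  levels <- threat_levels()
  assign <- rep(levels, n_each)
  if (rem > 0L) {
    warning("epochs_per_block not divisible by 3; using near-balanced threat assignment",
            call. = FALSE)
    assign <- c(assign, sample(levels, rem))
  }
  sample(assign)
}

#' Simulate a block of the approach-avoidance conflict task
#'
#' Runs `epochs_per_block` epochs with threat levels balanced across the
#' three levels and shuffled. Epochs follow each other on a continuous block
#' clock.
#'
#' @inheritParams simulate_task1_epoch
#' @param subject_id,block_id Identifiers stamped on the log.
#' @return An [event_log()] with `task = "task1"`.
#' @examples
#' cfg <- task_config()
#' log <- simulate_task1_block(cfg, approach_policy(), seed = 1)
#' table(log$kind)
#' @export
simulate_task1_block <- function(config, policy, seed = NULL,
                                 subject_id = "agent", block_id = 1L) {
  stopifnot(inherits(config, "task_config"))
  with_seed(seed, {
    threats <- balanced_threats(config$epochs_per_block)
    t0 <- 0
    parts <- vector("list", length(threats))
    for (e in seq_along(threats)) {
      ep <- simulate_task1_epoch(config, policy, threats[e],
                                 epoch_id = e, t0 = t0)
      t0 <- max(ep$t)
      parts[[e]] <- ep
    }
    event_log(do.call(rbind, parts), subject_id, block_id, "task1", config)
  })
}
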