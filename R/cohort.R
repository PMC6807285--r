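#' Cohort specification
#'
#' Describes a simulated study sample: `n_controls` control agents whose
#' policy parameters are drawn around a control mean, plus named patient
#' agents whose policies deviate from that mean by explicit perturbations
#' (the lesion-agent mechanism, e.g. an attenuated loss coefficient or a
#' slowed return latency). Also carries the parameters of the memory-rating
#' simulator: on a 0-100% visual-analogue scale, ratings are a linear
#' function of the true catch rate. Defaults `rating_slope = 0.99` and
#' `rating_bias = 36.3` reproduce a near-unit slope with a substantial
#' overestimation intercept, as observed in healthy players of this game.
#'
#' @param n_controls Number of control agents (>= 2).
#' @param patients Named list; each element is a list with optional elements
#'   `approach` and `exposure`, themselves named lists of policy parameters
#'   that override the control mean (e.g.
#'   `list(mtl = list(approach = list(approach_coef_loss = 0)))`).
#' @param control_policy_mean An [approach_policy()] giving the control mean.
#' @param control_policy_sd Named numeric vector of between-subject SDs for a
#'   subset of approach-policy parameters; parameters not named are fixed at
#'   the mean.
#' @param exposure_policy_mean An [exposure_policy()] for Task 2.
#' @param exposure_policy_sd Named numeric vector of between-subject SDs for
#'   exposure-policy parameters (on the natural scale; `w` is clipped to
#'   \[0, 1\] and `sigma`, `lam` to positive values).
#' @param rating_slope,rating_bias,rating_noise_sd Memory-rating model:
#'   rating = clip(slope * true_rate + bias + Normal(0, noise), 0, 100),
#'   in percent.
#' @param master_seed Integer; deterministically spawns one seed per subject.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 10L,
                        patients = list(),
                        control_policy_mean = approach_policy(),
                        control_policy_sd = c(approach_intercept = 0.3,
                                              approach_coef_threat = 0.15,
                                              approach_coef_loss = 0.1,
                                              al_base = 50, rl_base = 30),
                        exposure_policy_mean = exposure_policy(),
                        exposure_policy_sd = c(w = 0.05, mu = 40, sigma = 20),
                        rating_slope = 0.99,
                        rating_bias = 36.3,
                        rating_noise_sd = 5,
                        master_seed = 1L) {
  if (n_controls < 2L) stop("n_controls must be >= 2", call. = FALSE)
  if (length(patients) > 0) {
    if (is.null(names(patients)) || anyDuplicated(names(patients))) {
      stop("patients must be a uniquely named list", call. = FALSE)
    }
  }
  structure(list(n_controls = as.integer(n_controls),
                 patients = patients,
                 control_policy_mean = control_policy_mean,
                 control_policy_sd = control_policy_sd,
                 exposure_policy_mean = exposure_policy_mean,
                 exposure_policy_sd = exposure_policy_sd,
                 rating_slope = rating_slope,
                 rating_bias = rating_bias,
                 rating_noise_sd = rating_noise_sd,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

# apply named overrides / jitter to a policy object, revalidating
perturb_policy <- function(policy, overrides) {
  p <- unclass(policy)
  for (nm in names(overrides)) {
    if (!nm %in% names(p)) {
      stop(sprintf("unknown policy parameter '%s'", nm), call. = FALSE)
    }
    p[[nm]] <- overrides[[nm]]
  }
  do.call(if (inherits(policy, "exposure_policy")) exposure_policy else
    approach_policy, p[names(formals(
      if (inherits(policy, "exposure_policy")) exposure_policy else
        approach_policy))])
}

draw_control_policy <- function(mean_policy, sd) {
  p <- unclass(mean_policy)
  for (nm in names(sd)) {
    p[[nm]] <- stats::rnorm(1, p[[nm]], sd[[nm]])
  }
  if (inherits(mean_policy, "exposure_policy")) {
    p$w <- min(max(p$w, 0), 1)
    p$sigma <- max(p$sigma, 1)
    p$lam <- max(p$lam, 1e-6)
    exposure_policy(p$w, p$mu, p$sigma, p$lam, p$presses_per_epoch_mean)
  } else {
    p$latency_noise_sd <- max(p$latency_noise_sd, 1)
    do.call(approach_policy, p[names(formals(approach_policy))])
  }
}

#' Simulate a full cohort of agents
#'
#' Draws one approach policy (and, when `include_task2`, one exposure
#' policy) per control agent around the control mean, builds each patient's
#' policy by applying its perturbations to the control mean, and simulates
#' all Task-1 blocks (and optionally Task-2 blocks) for every subject. Every
#' subject gets a distinct seed derived from `master_seed`, so the whole
#' cohort is reproducible.
#'
#' @param spec A [cohort_spec()].
#' @param config A [task_config()].
#' @param include_task2 Also simulate the safe predator exposure blocks.
#' @return A list with `logs` (named by subject, each a list of
#'   [event_log()]s), `manifest` (data frame: subject_id, group, seed) and
#'   `policies` (named list of the realized policies).
#' @examples
#' spec <- cohort_spec(n_controls = 2, master_seed = 7)
#' cfg <- task_config(epochs_per_block = 9, n_blocks_task1 = 1)
#' coh <- simulate_cohort(spec, cfg)
#' coh$manifest
#' @export
simulate_cohort <- function(spec, config, include_task2 = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(config, "task_config"))
  labels <- c(sprintf("control_%02d", seq_len(spec$n_controls)),
              names(spec$patients))
  groups <- c(rep("control", spec$n_controls),
              vapply(names(spec$patients), function(x) x, character(1)))
  seeds <- with_seed(spec$master_seed,
                     sample.int(.Machine$integer.max, length(labels)))
  logs <- vector("list", length(labels))
  policies <- vector("list", length(labels))
  names(logs) <- names(policies) <- labels
  for (i in seq_along(labels)) {
    is_control <- groups[i] == "control"
    with_seed(seeds[i], {
      apol <- if (is_control) {
        draw_control_policy(spec$control_policy_mean, spec$control_policy_sd)
      } else {
        perturb_policy(spec$control_policy_mean,
                       spec$patients[[labels[i]]]$approach)
      }
      epol <- if (is_control) {
        draw_control_policy(spec$exposure_policy_mean, spec$exposure_policy_sd)
      } else {
        perturb_policy(spec$exposure_policy_mean,
                       spec$patients[[labels[i]]]$exposure)
      }
      blocks <- lapply(seq_len(config$n_blocks_task1), function(b) {
        simulate_task1_block(config, apol, subject_id = labels[i],
                             block_id = b)
      })
      if (include_task2) {
        blocks <- c(blocks, lapply(seq_len(config$n_blocks_task2), function(b) {
          simulate_task2_block(config, epol, subject_id = labels[i],
                               block_id = config$n_blocks_task1 + b)
        }))
      }
      logs[[i]] <- blocks
      policies[[i]] <- list(approach = apol, exposure = epol)
    })
  }
  list(logs = logs,
       manifest = data.frame(subject_id = labels, group = groups,
                             seed = seeds, stringsAsFactors = FALSE),
       policies = policies)
}

#' Simulate memory ratings of catch probability
#'
#' Visual-analogue-scale ratings (0-100%) of the per-threat catch
#' probability, generated as a noisy linear function of the true catch rate
#' and clipped to the scale.
#'
#' @param true_rates Numeric vector of true catch rates in percent (0-100).
#' @param spec A [cohort_spec()] carrying slope, bias and noise SD.
#' @param seed Optional integer seed.
#' @return Numeric vector of ratings in \[0, 100\], same length and names as
#'   `true_rates`.
#' @examples
#' simulate_memory_ratings(c(low = 10, med = 20, high = 35),
#'                         cohort_spec(rating_noise_sd = 0))
#' @export
simulate_memory_ratings <- function(true_rates, spec, seed = NULL) {
  stopifnot(all(is.na(true_rates) | (true_rates >= 0 & true_rates <= 100)))
  with_seed(seed, {
    noise <- if (spec$rating_noise_sd > 0) {
      stats::rnorm(length(true_rates), 0, spec$rating_noise_sd)
    } else 0
    pmin(pmax(spec$rating_slope * true_rates + spec$rating_bias + noise, 0),
         100)
  })
}
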