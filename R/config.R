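#' Task configuration for the approach-avoidance conflict game
#'
#' Bundles every generative constant of the two behavioral tasks: the
#' per-100-ms predator wake-up hazards for the three threat levels, block and
#' epoch structure, token timing, response-latency analysis windows, and the
#' exposure-task attempt limit.
#'
#' @param hazards Named numeric vector of predator activation probabilities
#'   per `step_ms` time step while the player is outside the safe place, one
#'   per threat level, strictly increasing, each in (0, 1).
#' @param n_blocks_task1 Number of approach-avoidance blocks per subject.
#' @param epochs_per_block Number of epochs (game rounds) per block.
#' @param tokens_per_epoch Number of token cycles scheduled per epoch.
#' @param availability_mean Mean (ms) of the exponential token availability
#'   duration.
#' @param wait_offset Constant (ms) added to the exponential draw for the
#'   waiting interval before each token.
#' @param approach_window Open interval (ms) outside which approach latencies
#'   are excluded from analysis.
#' @param return_window Open interval (ms) outside which return latencies are
#'   excluded from analysis.
#' @param exposure_attempts_max Maximum exposure attempts per epoch in the
#'   safe predator exposure task; further key presses are ignored.
#' @param exposure_epochs_per_block Number of exposure-task epochs per block.
#' @param n_blocks_task2 Number of exposure-task blocks per subject.
#' @param step_ms Width (ms) of the discrete hazard step.
#'
#' @return An object of class `task_config` (a validated list).
#' @examples
#' cfg <- task_config()
#' cfg$hazards
#' @export
task_config <- function(hazards = c(low = 0.1, med = 0.2, high = 0.3),
                        n_blocks_task1 = 4L,
                        epochs_per_block = 45L,
                        tokens_per_epoch = 6L,
                        availability_mean = 1250,
                        wait_offset = 500,
                        approach_window = c(150, 2000),
                        return_window = c(0, 2000),
                        exposure_attempts_max = 6L,
                        exposure_epochs_per_block = 36L,
                        n_blocks_task2 = 2L,
                        step_ms = 100) {
  cfg <- list(
    hazards = hazards,
    n_blocks_task1 = as.integer(n_blocks_task1),
    epochs_per_block = as.integer(epochs_per_block),
    tokens_per_epoch = as.integer(tokens_per_epoch),
    availability_mean = availability_mean,
    wait_offset = wait_offset,
    approach_window = approach_window,
    return_window = return_window,
    exposure_attempts_max = as.integer(exposure_attempts_max),
    exposure_epochs_per_block = as.integer(exposure_epochs_per_block),
    n_blocks_task2 = as.integer(n_blocks_task2),
    step_ms = step_ms
  )
  validate_task_config(cfg)
  class(cfg) <- "task_config"
  cfg
}

validate_task_config <- function(cfg) {
  h <- cfg$hazards
  if (length(h) != 3L || is.null(names(h)) ||
      !identical(names(h), c("low", "med", "high"))) {
    stop("`hazards` must be a named vector c(low = , med = , high = )",
         call. = FALSE)
  }
  if (any(!is.finite(h)) || any(h <= 0) || any(h >= 1)) {
    stop("hazards must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(diff(h) <= 0)) {
    stop("hazards must be strictly increasing in threat level", call. = FALSE)
  }
  times <- c(cfg$availability_mean, cfg$wait_offset, cfg$step_ms)
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("all task times must be finite and > 0", call. = FALSE)
  }
  counts <- c(cfg$n_blocks_task1, cfg$epochs_per_block, cfg$tokens_per_epoch,
              cfg$exposure_attempts_max, cfg$exposure_epochs_per_block,
              cfg$n_blocks_task2)
  if (any(counts < 1L)) stop("all counts must be >= 1", call. = FALSE)
  for (w in list(cfg$approach_window, cfg$return_window)) {
    if (length(w) != 2L || w[1] < 0 || w[2] <= w[1]) {
      stop("latency windows must be increasing pairs of non-negative times",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @export
print.task_config <- function(x, ...) {
  cat("Approach-avoidance task configuration\n")
  cat(sprintf("  hazards/100ms: low %.2f, med %.2f, high %.2f\n",
              x$hazards[1], x$hazards[2], x$hazards[3]))
  cat(sprintf("  task 1: %d blocks x %d epochs, %d tokens/epoch\n",
              x$n_blocks_task1, x$epochs_per_block, x$tokens_per_epoch))
  cat(sprintf("  token availability ~ Exp(mean %g ms); wait ~ Exp(mean %g ms) + %g ms\n",
              x$availability_mean, x$availability_mean, x$wait_offset))
  cat(sprintf("  task 2: %d blocks x %d epochs, max %d exposure attempts\n",
              x$n_blocks_task2, x$exposure_epochs_per_block,
              x$exposure_attempts_max))
  invisible(x)
}

#' Agent policy for the approach-avoidance task
#'
#' A stochastic agent standing in for a human player. The agent forages
#' sequentially within an epoch and stops at its first decline; the marginal
#' probability of going for the token at potential loss `l` has logit linear
#' in threat level (coded -1, 0, 1) and `l` (0-5). Approach and return
#' latencies are Gaussian around linear predictors in the same two condition
#' variables (approach truncated to the token's availability, return
#' truncated at 1 ms).
#'
#' Coefficient units: log-odds per unit predictor for the decision model,
#' ms per unit predictor for the latency models.
#'
#' @param approach_intercept,approach_coef_threat,approach_coef_loss Logistic
#'   decision model coefficients (log-odds).
#' @param al_base,al_coef_threat,al_coef_loss Approach latency location terms
#'   (ms); latency is measured from token onset to leaving the safe place.
#' @param rl_base,rl_coef_threat,rl_coef_loss Return latency location terms
#'   (ms); latency from token collection to re-entering the safe place.
#' @param latency_noise_sd Gaussian noise SD (ms) shared by both latencies.
#' @return An object of class `approach_policy`.
#' @examples
#' pol <- approach_policy(approach_coef_loss = -0.6)
#' @export
approach_policy <- function(approach_intercept = 2.2,
                            approach_coef_threat = -0.8,
                            approach_coef_loss = -0.45,
                            al_base = 450, al_coef_threat = -30,
                            al_coef_loss = -25,
                            rl_base = 150, rl_coef_threat = -10,
                            rl_coef_loss = -5,
                            latency_noise_sd = 80) {
  pol <- list(
    approach_intercept = approach_intercept,
    approach_coef_threat = approach_coef_threat,
    approach_coef_loss = approach_coef_loss,
    al_base = al_base, al_coef_threat = al_coef_threat,
    al_coef_loss = al_coef_loss,
    rl_base = rl_base, rl_coef_threat = rl_coef_threat,
    rl_coef_loss = rl_coef_loss,
    latency_noise_sd = latency_noise_sd
  )
  if (any(!is.finite(unlist(pol)))) {
    stop("approach policy parameters must all be finite", call. = FALSE)
  }
  if (latency_noise_sd < 0) stop("latency_noise_sd must be >= 0", call. = FALSE)
  class(pol) <- "approach_policy"
  pol
}

#' @export
print.approach_policy <- function(x, ...) {
  cat("Approach policy (logistic decision + linear latencies)\n")
  cat(sprintf("  logit(approach) = %.2f %+.2f*threat %+.2f*loss\n",
              x$approach_intercept, x$approach_coef_threat,
              x$approach_coef_loss))
  cat(sprintf("  approach latency: %g %+g*threat %+g*loss ms (sd %g)\n",
              x$al_base, x$al_coef_threat, x$al_coef_loss, x$latency_noise_sd))
  cat(sprintf("  return latency:   %g %+g*threat %+g*loss ms (sd %g)\n",
              x$rl_base, x$rl_coef_threat, x$rl_coef_loss, x$latency_noise_sd))
  invisible(x)
}

#' Agent policy for the safe predator exposure task
#'
#' Generates exposure key presses from a two-component process: with
#' probability `w` a press time is drawn uniformly over the epoch timeline
#' (token-unrelated null process), otherwise it is an exponentially modified
#' Gaussian (exGauss) reaction to a token onset.
#'
#' @param w Weight in \[0, 1\] of the token-unrelated uniform process.
#' @param mu,sigma Gaussian component mean and SD (ms) of the exGauss.
#' @param lam Exponential component rate (1/ms) of the exGauss.
#' @param presses_per_epoch_mean Mean number of intended presses per epoch
#'   (Poisson); the task caps the emitted attempts.
#' @return An object of class `exposure_policy`.
#' @export
exposure_policy <- function(w = 0.3, mu = 400, sigma = 100, lam = 1 / 500,
                            presses_per_epoch_mean = 3) {
  if (!is.finite(w) || w < 0 || w > 1) {
    stop("`w` must lie in [0, 1]", call. = FALSE)
  }
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (lam <= 0) stop("`lam` must be > 0", call. = FALSE)
  if (presses_per_epoch_mean < 0) {
    stop("`presses_per_epoch_mean` must be >= 0", call. = FALSE)
  }
  structure(list(w = w, mu = mu, sigma = sigma, lam = lam,
                 presses_per_epoch_mean = presses_per_epoch_mean),
            class = "exposure_policy")
}

#' @export
print.exposure_policy <- function(x, ...) {
  cat(sprintf(
    "Exposure policy: w = %.2f uniform + %.2f exGauss(mu %g ms, sigma %g ms, rate %g /ms)\n",
    x$w, 1 - x$w, x$mu, x$sigma, x$lam))
  invisible(x)
}

# threat level helpers -------------------------------------------------------

threat_levels <- function() c("low", "med", "high")

#' Numeric coding of threat level
#'
#' Maps the three threat levels to the centered linear codes -1, 0, 1 used in
#' the agent policies and in linear contrasts.
#'
#' @param threat Character vector of threat levels ("low", "med", "high").
#' @return Numeric vector in \{-1, 0, 1\}.
#' @export
threat_code <- function(threat) {
  code <- c(low = -1, med = 0, high = 1)[as.character(threat)]
  if (any(is.na(code))) stop("unknown threat level", call. = FALSE)
  unname(code)
}

# seed scoping: run expr under a temporary RNG state when seed is given
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
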