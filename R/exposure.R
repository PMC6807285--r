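#' Exposure-time latencies from a Task-2 event log
#'
#' For every exposure key press made after the first token of its epoch, the
#' latency `T2` is the time since the most recent preceding token onset.
#' Presses made before the first token are excluded from the latency set but
#' counted. Per-epoch press and token times are retained so that permutation
#' null distributions can be built from the same object.
#'
#' @param logs A Task-2 [event_log()] or a list of them (one subject).
#' @return An object of class `exposure_latencies`: list with `subject_id`,
#'   `t2` (ms), `n_pre` (presses before the first token), `n_press` (all
#'   presses) and `epochs` (per-epoch press/token times on a common clock).
#' @examples
#' log <- simulate_task2_block(task_config(), exposure_policy(), seed = 1)
#' el <- exposure_latencies(log)
#' c(n = el$n_press, pre = el$n_pre)
#' @export
exposure_latencies <- function(logs) {
  if (inherits(logs, "event_log")) logs <- list(logs)
  subject <- attr(logs[[1]], "subject_id")
  t2 <- numeric(0)
  n_pre <- 0L
  n_press <- 0L
  epochs <- list()
  for (log in logs) {
    assert_task(log, "task2")
    for (e in epoch_split(log)) {
      tok <- sort(e$t[e$kind == "token_on"])
      press <- sort(e$t[e$kind == "key_up"])
      n_press <- n_press + length(press)
      if (length(press) == 0) next
      if (length(tok) == 0) {
        n_pre <- n_pre + length(press)
      } else {
        pre <- press < tok[1]
        n_pre <- n_pre + sum(pre)
        for (p in press[!pre]) {
          t2 <- c(t2, p - max(tok[tok <= p]))
        }
      }
      epochs[[length(epochs) + 1L]] <-
        list(start = e$t[e$kind == "epoch_start"][1],
             end = e$t[e$kind == "epoch_end"][1],
             token_t = tok, press_t = press)
    }
  }
  structure(list(subject_id = subject, t2 = t2, n_pre = n_pre,
                 n_press = n_press, epochs = epochs),
            class = "exposure_latencies")
}

#' @export
print.exposure_latencies <- function(x, ...) {
  cat(sprintf(
    "<exposure_latencies> subject %s: %d presses (%d before first token), median T2 %.0f ms\n",
    x$subject_id, x$n_press, x$n_pre,
    if (length(x$t2)) stats::median(x$t2) else NA))
  invisible(x)
}

#' Null distributions of exposure times under token independence
#'
#' Two empirical nulls for the hypothesis that exposure key presses are
#' unrelated to token onsets. `uniform_time` simulates fresh epoch timelines
#' from the task timing model and scatters presses uniformly over each
#' epoch; `permutation` re-pairs the observed press times (relative to epoch
#' start) with the token streams of randomly chosen *other* observed epochs.
#' In both cases press-to-last-token latencies are accumulated into an
#' empirical distribution on a fixed grid.
#'
#' @param config A [task_config()] (timing model for `uniform_time`).
#' @param method "uniform_time" or "permutation".
#' @param n_sim Number of simulated epochs (`uniform_time`) or re-pairing
#'   replicates (`permutation`).
#' @param seed Optional integer seed.
#' @param exposure For `method = "permutation"`: an [exposure_latencies()]
#'   object (or list of them) providing the observed epochs.
#' @param presses_per_epoch Uniform presses scattered per simulated epoch
#'   (`uniform_time` only).
#' @param bin_ms Histogram bin width (ms) of the stored density.
#' @return An object of class `exposure_null`: method, sorted `samples`,
#'   `breaks`, `density` (per ms, integrating to 1), `n_sim`, `seed`.
#' @export
build_null_distribution <- function(config,
                                    method = c("uniform_time", "permutation"),
                                    n_sim = 2000, seed = NULL,
                                    exposure = NULL,
                                    presses_per_epoch = 10,
                                    bin_ms = 50) {
  method <- match.arg(method)
  samples <- with_seed(seed, {
    if (method == "uniform_time") {
      stopifnot(inherits(config, "task_config"))
      rate <- 1 / config$availability_mean
      out <- vector("list", n_sim)
      for (i in seq_len(n_sim)) {
        n_tok <- config$tokens_per_epoch
        waits <- stats::rexp(n_tok, rate) + config$wait_offset
        avails <- stats::rexp(n_tok, rate)
        t_on <- cumsum(waits + c(0, avails[-n_tok]))
        dur <- t_on[n_tok] + avails[n_tok]
        press <- stats::runif(presses_per_epoch, 0, dur)
        press <- press[press >= t_on[1]]
        out[[i]] <- vapply(press, function(p) p - max(t_on[t_on <= p]),
                           numeric(1))
      }
      unlist(out)
    } else {
      if (is.null(exposure)) {
        stop("method = 'permutation' needs observed `exposure` data",
             call. = FALSE)
      }
      if (inherits(exposure, "exposure_latencies")) exposure <- list(exposure)
      epochs <- do.call(c, lapply(exposure, `[[`, "epochs"))
      if (length(epochs) < 2) stop("need >= 2 observed epochs", call. = FALSE)
      out <- vector("list", n_sim)
      for (i in seq_len(n_sim)) {
        pair <- sample.int(length(epochs), 2)
        src <- epochs[[pair[1]]]; tgt <- epochs[[pair[2]]]
        press_rel <- src$press_t - src$start
        tok_rel <- tgt$token_t - tgt$start
        press_rel <- press_rel[press_rel <= tgt$end - tgt$start]
        if (length(tok_rel) == 0) next
        press_rel <- press_rel[press_rel >= tok_rel[1]]
        out[[i]] <- vapply(press_rel,
                           function(p) p - max(tok_rel[tok_rel <= p]),
                           numeric(1))
      }
      unlist(out)
    }
  })
  if (length(samples) < 1e4) {
    warning(sprintf(
      "only %d null T2 samples; tail estimates may be unstable",
      length(samples)), call. = FALSE)
  }
  samples <- sort(samples)
  breaks <- seq(0, max(samples) + bin_ms, by = bin_ms)
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  structure(list(method = method, samples = samples, breaks = breaks,
                 density = h$density, n_sim = n_sim, seed = seed),
            class = "exposure_null")
}

#' @export
print.exposure_null <- function(x, ...) {
  cat(sprintf(
    "<exposure_null> %s: %d T2 samples over [0, %.0f] ms (%d simulations)\n",
    x$method, length(x$samples), max(x$breaks), x$n_sim))
  invisible(x)
}

#' Evaluate the empirical null density / CDF
#'
#' @param null An `exposure_null`.
#' @param t Times (ms).
#' @return Density per ms (`null_pdf`) or cumulative probability
#'   (`null_cdf`); zero density outside the observed support.
#' @export
null_pdf <- function(null, t) {
  idx <- findInterval(t, null$breaks, rightmost.closed = TRUE)
  d <- rep(0, length(t))
  ok <- idx >= 1 & idx <= length(null$density)
  d[ok] <- null$density[idx[ok]]
  d
}

#' @rdname null_pdf
#' @export
null_cdf <- function(null, t) {
  stats::ecdf(null$samples)(t)
}

#' Kolmogorov-Smirnov and t tests on exposure times
#'
#' One-sample KS of each group's pooled exposure times against the empirical
#' null CDF; between two groups, additionally a two-sample KS test on pooled
#' times and a two-sample t test on per-subject mean exposure times. All
#' tests are delegated to the standard \pkg{stats} routines.
#'
#' @param sets_a,sets_b Lists of [exposure_latencies()] (one per subject);
#'   `sets_b` optional.
#' @param null An `exposure_null` from [build_null_distribution()].
#' @return List with `one_sample` (per group), and when two groups are
#'   given, `two_sample_ks` and `mean_t_test`.
#' @export
ks_exposure_tests <- function(sets_a, sets_b = NULL, null) {
  pool <- function(sets) unlist(lapply(sets, `[[`, "t2"))
  xa <- pool(sets_a)
  if (length(xa) < 5) stop("need >= 5 exposure times per sample",
                           call. = FALSE)
  one_a <- suppressWarnings(
    stats::ks.test(xa, function(q) null_cdf(null, q)))
  out <- list(one_sample = list(a = one_a))
  if (!is.null(sets_b)) {
    xb <- pool(sets_b)
    if (length(xb) < 5) stop("need >= 5 exposure times per sample",
                             call. = FALSE)
    out$one_sample$b <- suppressWarnings(
      stats::ks.test(xb, function(q) null_cdf(null, q)))
    out$two_sample_ks <- suppressWarnings(stats::ks.test(xa, xb))
    means_a <- vapply(sets_a, function(s) mean(s$t2), numeric(1))
    means_b <- vapply(sets_b, function(s) mean(s$t2), numeric(1))
    # Welch t test needs >= 2 subjects per group
    out$mean_t_test <- if (length(means_a) >= 2 && length(means_b) >= 2) {
      stats::t.test(means_a, means_b)
    } else NULL
  }
  out
}
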