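test_that("identical config, policy and seed give byte-identical logs", {
  cfg <- task_config(epochs_per_block = 9)
  pol <- approach_policy()
  a <- simulate_task1_block(cfg, pol, seed = 42)
  b <- simulate_task1_block(cfg, pol, seed = 42)
  expect_identical(a, b)
  c <- simulate_task1_block(cfg, pol, seed = 43)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("an agent that never approaches never leaves, collects or is caught", {
  cfg <- task_config(epochs_per_block = 9)
  pol <- approach_policy(approach_intercept = -1e3)
  log <- simulate_task1_block(cfg, pol, seed = 1)
  expect_false(any(log$kind %in% c("leave_safe", "token_collected",
                                   "caught", "enter_safe")))
  expect_equal(sum(log$kind == "token_on"), 9 * cfg$tokens_per_epoch)
})

test_that("catch probability over a fixed exposure matches the closed-form survival product", {
  # agent held outside for 1000 ms at high threat: 10 hazard steps at 0.3
  p_expected <- 1 - 0.7^10
  cfg <- task_config()
  pol <- approach_policy(approach_intercept = 1e3, approach_coef_threat = 0,
                         approach_coef_loss = 0, al_base = 100,
                         al_coef_threat = 0, al_coef_loss = 0,
                         rl_base = 1050, rl_coef_threat = 0,
                         rl_coef_loss = 0, latency_noise_sd = 0)
  set.seed(7)
  exc <- 0L; caught <- 0L
  for (i in 1:500) {
    ep <- simulate_task1_epoch(cfg, pol, "high", epoch_id = i)
    exc <- exc + sum(ep$kind == "leave_safe")
    caught <- caught + sum(ep$kind == "caught")
  }
  p_hat <- caught / exc
  se <- sqrt(p_expected * (1 - p_expected) / exc)
  expect_lt(abs(p_hat - p_expected), 3 * se + 1e-12)
})

test_that("token availability and inter-token waits follow the configured timing", {
  cfg <- task_config(epochs_per_block = 300)
  pol <- approach_policy(approach_intercept = -1e3)  # tokens always expire
  log <- simulate_task1_block(cfg, pol, seed = 5)
  on <- log[log$kind == "token_on", ]
  off <- log[log$kind == "token_off", ]
  stopifnot(nrow(on) == nrow(off))
  avail <- off$t - on$t
  expect_gte(length(avail), 1500)
  se <- sd(avail) / sqrt(length(avail))
  expect_lt(abs(mean(avail) - cfg$availability_mean), 3 * se)
  # waits: from epoch start (first token) or previous token_off
  prev_end <- c(0, off$t[-nrow(off)])
  starts <- log$t[log$kind == "epoch_start"]
  first <- !duplicated(on$epoch_id)
  prev_end[first] <- starts[on$epoch_id[first]]
  waits <- on$t - prev_end
  se_w <- sd(waits) / sqrt(length(waits))
  expect_lt(abs(mean(waits) - (cfg$availability_mean + cfg$wait_offset)),
            3 * se_w)
})

test_that("blocks balance threat levels and warn when they cannot", {
  cfg <- task_config()
  log <- simulate_task1_block(cfg, approach_policy(), seed = 2)
  eps <- unique(as.data.frame(log)[, c("epoch_id", "threat_level")])
  expect_equal(nrow(eps), 45)
  expect_equal(as.integer(table(eps$threat_level)[c("low", "med", "high")]),
               c(15L, 15L, 15L))
  cfg3 <- task_config(epochs_per_block = 3)
  log3 <- simulate_task1_block(cfg3, approach_policy(), seed = 2)
  expect_setequal(unique(log3$threat_level), c("low", "med", "high"))
  cfg4 <- task_config(epochs_per_block = 4)
  expect_warning(simulate_task1_block(cfg4, approach_policy(), seed = 2),
                 "near-balanced")
})

test_that("token accounting and catch placement invariants hold across epochs", {
  cfg <- task_config(epochs_per_block = 45)
  log <- simulate_task1_block(cfg, approach_policy(), seed = 11)
  for (e in split(as.data.frame(log), log$epoch_id)) {
    coll <- e[e$kind == "token_collected", ]
    n_caught <- sum(e$kind == "caught")
    expect_lte(n_caught, 1)
    if (n_caught == 1) {
      t_caught <- e$t[e$kind == "caught"]
      # caught strictly inside a leave_safe -> (enter_safe | end) excursion
      t_leave <- max(e$t[e$kind == "leave_safe" & e$t <= t_caught])
      expect_true(is.finite(t_leave))
      expect_false(any(e$kind == "enter_safe" & e$t > t_leave &
                         e$t < t_caught))
      # no collections after the catch
      expect_false(any(coll$t > t_caught))
      # tokens retained = collected - lost, never negative
      lost <- nrow(coll)  # all held tokens forfeited
      expect_gte(nrow(coll) - lost, 0)
    }
    # at most tokens_per_epoch token_on events
    expect_lte(sum(e$kind == "token_on"), cfg$tokens_per_epoch)
  }
})

test_that("per-step activation hazard converges to the configured hazard at every level", {
  cfg <- task_config()
  for (lev in c("low", "med", "high")) {
    pol <- approach_policy(approach_intercept = 1e3, approach_coef_threat = 0,
                           approach_coef_loss = 0, al_base = 100,
                           al_coef_threat = 0, al_coef_loss = 0,
                           rl_base = 450, rl_coef_threat = 0,
                           rl_coef_loss = 0, latency_noise_sd = 0)
    set.seed(13)
    steps <- 0; act <- 0
    for (i in 1:900) {
      ep <- simulate_task1_epoch(cfg, pol, lev, epoch_id = i)
      t_leave <- ep$t[ep$kind == "leave_safe"]
      for (tl in t_leave) {
        t_caught <- ep$t[ep$kind == "caught" & ep$t > tl]
        t_enter <- ep$t[ep$kind == "enter_safe" & ep$t > tl]
        t_end <- min(c(t_caught, t_enter))
        if (length(t_caught) && t_end == min(t_caught)) {
          k <- round((t_end - tl) / cfg$step_ms)
          steps <- steps + k; act <- act + 1
        } else {
          steps <- steps + floor((t_end - tl) / cfg$step_ms)
        }
      }
    }
    p <- cfg$hazards[[lev]]
    se <- sqrt(p * (1 - p) / steps)
    expect_gt(steps, 1500)
    expect_lt(abs(act / steps - p), 3 * se)
  }
})
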