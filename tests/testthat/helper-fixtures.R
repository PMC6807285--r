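# shared fixtures and independent oracles, all built in code

# hand-built task-1 epoch: n_collected tokens collected in order, optionally
# ending in a catch on the excursion of the last collected token
manual_epoch <- function(epoch_id, threat, n_collected, caught = FALSE,
                         t0 = 0, approach_ms = 500, return_ms = 300,
                         n_tokens = 6) {
  rows <- list()
  add <- function(t, kind, idx = NA_integer_, side = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      t = t, kind = kind, epoch_id = epoch_id, threat_level = threat,
      token_index = idx, side = side, stringsAsFactors = FALSE)
  }
  add(t0, "epoch_start")
  t <- t0
  for (i in seq_len(n_tokens)) {
    t_on <- t + 1000
    add(t_on, "token_on", i, "left")
    if (i <= n_collected) {
      t_press <- t_on + approach_ms
      add(t_press, "leave_safe", i, "left")
      add(t_press, "token_collected", i, "left")
      if (caught && i == n_collected) {
        add(t_press + 100, "predator_wake", i)
        add(t_press + 100, "caught", i)
        t <- t_press + 100
      } else {
        add(t_press + return_ms, "enter_safe", i, "left")
        t <- t_press + return_ms
      }
    } else {
      add(t_on + 800, "token_off", i, "left")
      t <- t_on + 800
    }
  }
  add(t, "epoch_end")
  do.call(rbind, rows)
}

manual_task1_log <- function(epochs, config = task_config(),
                             subject = "manual") {
  event_log(do.call(rbind, epochs), subject, 1L, "task1", config)
}

# hand-built task-2 epoch: given token onset times and press times
manual_task2_epoch <- function(epoch_id, token_t, press_t, duration,
                               threat = "med", t0 = 0) {
  df <- data.frame(
    t = c(t0, t0 + token_t, t0 + token_t + 200,
          t0 + press_t, t0 + press_t, t0 + duration),
    kind = c("epoch_start", rep("token_on", length(token_t)),
             rep("token_off", length(token_t)),
             rep("key_up", length(press_t)),
             rep("expose_fail", length(press_t)), "epoch_end"),
    epoch_id = epoch_id, threat_level = threat,
    token_index = NA_integer_, side = NA_character_,
    stringsAsFactors = FALSE)
  df[order(df$t), ]
}

manual_task2_log <- function(epochs, config = task_config(),
                             subject = "manual") {
  event_log(do.call(rbind, epochs), subject, 1L, "task2", config)
}

# exact one-sided p of the ordinal dissociation statistic by full enumeration
# over the joint exchangeability pmf (small control groups only)
exact_dissociation_p <- function(observed, sizes_a, sizes_b,
                                 sidedness = "one") {
  grids <- lapply(c(sizes_a, sizes_b), function(n) 100 * (0:n) / n)
  combos <- do.call(expand.grid, grids)
  na <- length(sizes_a)
  diff <- rowMeans(combos[, seq_len(na), drop = FALSE]) -
    rowMeans(combos[, na + seq_along(sizes_b), drop = FALSE])
  prob <- 1 / prod(vapply(c(sizes_a, sizes_b), function(n) n + 1, numeric(1)))
  if (sidedness == "one") sum(diff >= observed) * prob else
    sum(abs(diff) >= abs(observed)) * prob
}

# textbook Greenhouse-Geisser epsilon via eigenvalues of the doubly centered
# covariance (independent of the contrast-matrix route in the package)
eigen_gg_epsilon <- function(m) {
  S <- cov(m)
  k <- ncol(S)
  Jc <- diag(k) - matrix(1 / k, k, k)
  D <- Jc %*% S %*% Jc
  lam <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  sum(lam)^2 / ((k - 1) * sum(lam^2))
}

# n x k matrix whose sample covariance equals `S` exactly
matrix_with_cov <- function(n, S, seed = 1) {
  k <- ncol(S)
  set.seed(seed)
  Z <- matrix(rnorm(n * k), n, k)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- qr.Q(qr(Z))[, seq_len(k)] * sqrt(n - 1)
  Z %*% chol(S)
}
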