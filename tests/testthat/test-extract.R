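test_that("decision reconstruction applies the cumulative scoring rule", {
  log <- manual_task1_log(list(
    manual_epoch(1, "low", n_collected = 2),
    manual_epoch(2, "med", n_collected = 3, caught = TRUE),
    manual_epoch(3, "high", n_collected = 6)))
  dec <- reconstruct_decisions(log)
  expect_equal(dec$approached[dec$epoch_id == 1], c(1, 1, 0, 0, 0, 0))
  expect_equal(nrow(dec[dec$epoch_id == 2, ]), 0)  # caught: not analyzable
  expect_equal(dec$approached[dec$epoch_id == 3], rep(1, 6))
  expect_equal(dec$potential_loss, rep(0:5, 2))
  # exactly six records per uncaught epoch
  expect_equal(as.integer(table(dec$epoch_id)), c(6L, 6L))
})

test_that("reconstruction inverts the simulator's collection counts on uncaught epochs", {
  cfg <- task_config(epochs_per_block = 45)
  log <- simulate_task1_block(cfg, approach_policy(), seed = 8)
  dec <- reconstruct_decisions(log)
  df <- as.data.frame(log)
  for (e in split(df, df$epoch_id)) {
    id <- e$epoch_id[1]
    if (any(e$kind == "caught")) {
      expect_false(id %in% dec$epoch_id)
    } else {
      rows <- dec[dec$epoch_id == id, ]
      expect_equal(nrow(rows), 6)
      expect_equal(sum(rows$approached), sum(e$kind == "token_collected"))
      expect_true(all(diff(rows$approached) <= 0))  # non-increasing
    }
  }
})

test_that("malformed epochs are skipped with a warning", {
  ep <- manual_epoch(1, "low", 2)
  broken <- rbind(ep, manual_epoch(2, "med", 1)[1:4, ])  # no epoch_end
  log <- event_log(broken, "s", 1L, "task1", task_config())
  expect_warning(dec <- reconstruct_decisions(log), "malformed")
  expect_equal(unique(dec$epoch_id), 1)
})

test_that("latency windows are strict and the sixth token is excluded", {
  cfg <- task_config()
  log <- manual_task1_log(list(
    manual_epoch(1, "low", 3, approach_ms = 100),   # below the 150 ms bound
    manual_epoch(2, "med", 2, approach_ms = 500, return_ms = 300),
    manual_epoch(3, "high", 6)))
  lat <- extract_latencies(log, cfg)
  e1 <- lat[lat$epoch_id == 1, ]
  expect_true(all(is.na(e1$approach_latency_ms)))
  expect_true(all(e1$approach_excluded))
  e2 <- lat[lat$epoch_id == 2, ]
  expect_equal(e2$approach_latency_ms, c(500, 500))
  expect_equal(e2$return_latency_ms, c(300, 300))
  expect_false(any(e2$approach_excluded | e2$return_excluded))
  # boundary values excluded under strict inequalities
  lb <- manual_task1_log(list(manual_epoch(1, "low", 1, approach_ms = 150),
                              manual_epoch(2, "low", 1, approach_ms = 1999.5,
                                           return_ms = 2000)))
  ll <- extract_latencies(lb, cfg)
  expect_true(is.na(ll$approach_latency_ms[1]))
  expect_equal(ll$approach_latency_ms[2], 1999.5)
  expect_true(is.na(ll$return_latency_ms[2]))
  # sixth token: no record
  expect_equal(max(lat$potential_loss), 4)
  expect_equal(nrow(lat[lat$epoch_id == 3, ]), 5)
})

test_that("return latency is absent when the excursion ended in a catch", {
  log <- manual_task1_log(list(manual_epoch(1, "med", 3, caught = TRUE)))
  lat <- extract_latencies(log, task_config())
  expect_equal(nrow(lat), 3)
  expect_true(is.na(lat$return_latency_ms[3]))
  expect_true(lat$caught[3])
  expect_false(lat$return_excluded[3])  # absence by catch is not an exclusion
})

test_that("orphan collection events are an error", {
  ep <- manual_epoch(1, "low", 1)
  ep <- ep[ep$kind != "token_on", ]
  log <- event_log(ep, "s", 1L, "task1", task_config())
  expect_error(extract_latencies(log, task_config()), "orphan")
})

test_that("true catch rates match raw event counts", {
  eps <- c(lapply(1:10, function(i) manual_epoch(i, "med", 1,
                                                 caught = i <= 3)),
           list(manual_epoch(11, "low", 0)))
  log <- manual_task1_log(eps)
  tc <- true_catch_rates(log)
  expect_equal(tc$rate[tc$threat_level == "med"], 30)
  expect_equal(tc$excursions[tc$threat_level == "med"], 10)
  expect_true(is.na(tc$rate[tc$threat_level == "low"]))   # no excursions
  expect_true(is.na(tc$rate[tc$threat_level == "high"]))
  # never-approach agent: all levels undefined
  pol0 <- approach_policy(approach_intercept = -1e3)
  log0 <- simulate_task1_block(task_config(epochs_per_block = 9), pol0,
                               seed = 1)
  expect_true(all(is.na(true_catch_rates(log0)$rate)))
})

test_that("performance QC excludes only clear low performers", {
  res <- performance_qc(c(a = 100, b = 102, c = 98, d = 5))
  expect_equal(res$excluded, "d")
  expect_setequal(res$kept, c("a", "b", "c"))
  # direct leave-one-out z of the excluded subject
  z_d <- (5 - mean(c(100, 102, 98))) / sd(c(100, 102, 98))
  expect_lt(z_d, -4)
  expect_equal(performance_qc(c(a = 50, b = 50, c = 50))$excluded,
               character(0))  # zero SD: no exclusion
  expect_equal(performance_qc(c(a = 100, b = 90, c = 2),
                              sd_threshold = Inf)$excluded, character(0))
  expect_error(performance_qc(c(a = 1, b = 2)), ">= 3")
})

test_that("condition means cover the 18-cell design and flag empty cells", {
  dec_all1 <- data.frame(subject_id = "s", epoch_id = rep(1:3, each = 6),
                         threat_level = rep(c("low", "med", "high"), each = 6),
                         token_index = rep(1:6, 3),
                         potential_loss = rep(0:5, 3),
                         approached = 1L)
  cm <- condition_means(dec_all1)
  expect_equal(nrow(cm), 18)
  expect_true(all(cm$approach_proportion == 1))
  # alternating epochs with 0 vs 6 tokens collected -> every cell 0.5
  dec_alt <- do.call(rbind, lapply(1:12, function(i) {
    k <- if (i %% 2 == 0) 6L else 0L
    data.frame(subject_id = "s", epoch_id = i,
               threat_level = c("low", "med", "high")[(i - 1) %% 3 + 1],
               token_index = 1:6, potential_loss = 0:5,
               approached = as.integer(1:6 <= k))
  }))
  cm_alt <- condition_means(dec_alt)
  expect_true(all(cm_alt$approach_proportion == 0.5))
  # single epoch: only its threat level has data
  cm1 <- condition_means(dec_all1[dec_all1$epoch_id == 1, ])
  expect_false(any(cm1$empty[cm1$threat_level == "low"]))
  expect_true(all(cm1$empty[cm1$threat_level != "low"]))
})

test_that("approach-and-survive counts respect catches", {
  log <- manual_task1_log(list(manual_epoch(1, "low", 3),
                               manual_epoch(2, "med", 2, caught = TRUE)))
  # epoch 1: 3 survived; epoch 2: 2 collected, 1 excursion caught -> 1
  expect_equal(approach_survival_count(log), 4)
})
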