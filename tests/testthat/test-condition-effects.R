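test_that("GG epsilon is exact in the two analytic regimes", {
  # compound symmetry: sample covariance constructed to be exactly spherical
  S_cs <- diag(4) * 2 + matrix(0.5, 4, 4)
  m_cs <- matrix_with_cov(12, S_cs, seed = 2)
  expect_equal(gg_epsilon(m_cs), 1, tolerance = 1e-10)
  # all variance in one contrast, k = 3: epsilon = 1/(k-1) = 0.5
  z <- rnorm(10)
  m_r1 <- 3 + outer(z, c(1, 0, -1))
  expect_equal(gg_epsilon(m_r1), 0.5, tolerance = 1e-10)
})

test_that("GG epsilon matches the eigenvalue formulation on arbitrary data", {
  set.seed(14)
  for (k in c(3, 4, 6)) {
    m <- matrix(rnorm(15 * k), 15, k) %*% matrix(rnorm(k * k), k)
    expect_equal(gg_epsilon(m), eigen_gg_epsilon(m), tolerance = 1e-10)
  }
})

test_that("the condition LME recovers a generative negative loss effect", {
  cfg <- task_config(n_blocks_task1 = 2)
  spec <- cohort_spec(n_controls = 10, master_seed = 41)
  coh <- simulate_cohort(spec, cfg)
  dec <- do.call(rbind, lapply(names(coh$logs), function(s)
    do.call(rbind, lapply(coh$logs[[s]], reconstruct_decisions))))
  cm <- condition_means(dec)
  fit <- fit_condition_lme(cm, "approach_proportion")
  a <- fit$anova
  expect_lt(a$p_gg[a$effect == "loss_f"], 0.001)
  loss_row <- fit$contrasts[fit$contrasts$term == "loss_n", ]
  expect_lt(loss_row$estimate, 0)
  expect_lt(loss_row$p, 0.001)
  # GG correction only weakens evidence for within-subject effects
  within <- !is.na(a$epsilon)
  expect_true(all(a$p_gg[within] >= a$p[within] - 1e-12))
  expect_true(all(a$epsilon[within] >= 0.2 & a$epsilon[within] <= 1))
})

test_that("a single subject is rejected", {
  d <- data.frame(subject_id = "only", threat_level = "low",
                  potential_loss = 0:5,
                  approach_proportion = seq(1, 0.5, length.out = 6))
  expect_error(fit_condition_lme(d, "approach_proportion"), ">= 2 subjects")
})

test_that("the loss test is calibrated under within-subject permutation of condition labels", {
  cfg <- task_config(n_blocks_task1 = 1)
  spec <- cohort_spec(n_controls = 6, master_seed = 43)
  coh <- simulate_cohort(spec, cfg)
  dec <- do.call(rbind, lapply(names(coh$logs), function(s)
    do.call(rbind, lapply(coh$logs[[s]], reconstruct_decisions))))
  cm <- condition_means(dec)
  set.seed(44)
  pvals <- replicate(24, {
    perm <- cm
    for (s in unique(perm$subject_id)) {
      i <- which(perm$subject_id == s)
      perm$approach_proportion[i] <- sample(perm$approach_proportion[i])
    }
    fit <- fit_condition_lme(perm, "approach_proportion")
    fit$contrasts$p[fit$contrasts$term == "loss_n"]
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("subject summaries are exact on analytic data and order-invariant", {
  d <- data.frame(subject_id = "s1", threat_level = "med",
                  potential_loss = 0:5,
                  approach_proportion = c(1, .8, .6, .4, .2, 0))
  expect_equal(subject_summary(d, "loss_linear_coefficient")$value, -0.2)
  d2 <- d; d2$approach_proportion <- 0.7
  expect_equal(subject_summary(d2, "loss_linear_coefficient")$value, 0)
  expect_equal(subject_summary(d2, "overall_mean")$value, 0.7)
  shuffled <- d[sample(nrow(d)), ]
  expect_equal(subject_summary(shuffled, "loss_linear_coefficient")$value,
               -0.2)
})

test_that("latency outcomes fit on single-trial tables", {
  cfg <- task_config(n_blocks_task1 = 2)
  spec <- cohort_spec(n_controls = 6, master_seed = 45)
  coh <- simulate_cohort(spec, cfg)
  lat <- do.call(rbind, lapply(names(coh$logs), function(s)
    do.call(rbind, lapply(coh$logs[[s]], function(l)
      extract_latencies(l, cfg)))))
  fit <- fit_condition_lme(lat, "approach_latency")
  expect_true(all(is.na(fit$anova$epsilon)))  # GG only for the action model
  expect_true(all(fit$anova$p >= 0 & fit$anova$p <= 1))
  al_loss <- fit$contrasts[fit$contrasts$term == "loss_n", ]
  expect_lt(al_loss$estimate, 0)  # faster approach at higher potential loss
})
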