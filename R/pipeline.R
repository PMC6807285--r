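#' Default pipeline configuration
#'
#' A lesion-study-analogue design: three cohorts, each a set of lesion
#' agents with its own matched control group — three agents with broad
#' medial-temporal-like perturbations (10 controls, with exposure-task
#' blocks), one agent with a selective hippocampus-like perturbation
#' (9 controls, with exposure-task blocks) and one agent with a selective
#' amygdala-like perturbation (24 controls, conflict task only). The
#' MTL-like and HC-like agents carry an attenuated potential-loss
#' sensitivity; the MTL-like agents additionally a flattened threat
#' sensitivity and a slower exposure-response decay (smaller exGauss rate);
#' the amygdala-like agent a slowed return from the token.
#'
#' @return A nested list consumable by [run_pipeline()]; serialize with
#'   `yaml::write_yaml()` to edit on disk.
#' @export
default_pipeline_config <- function() {
  mtl_perturb <- list(
    approach = list(approach_coef_loss = -0.15, approach_coef_threat = -0.3),
    exposure = list(lam = 1 / 900))
  list(
    task = list(),
    cohorts = list(
      mtl = list(n_controls = 10, include_task2 = TRUE,
                 patients = list(mtl_1 = mtl_perturb, mtl_2 = mtl_perturb,
                                 mtl_3 = mtl_perturb)),
      hc = list(n_controls = 9, include_task2 = TRUE,
                patients = list(hc_1 = list(
                  approach = list(approach_coef_loss = -0.15),
                  exposure = list(lam = 1 / 800)))),
      amy = list(n_controls = 24, include_task2 = FALSE,
                 patients = list(amy_1 = list(
                   approach = list(rl_base = 400))))
    ),
    analysis = list(
      summary_statistic = "loss_linear_coefficient",
      dissociation = list(n_sim = 10000, sidedness = "one"),
      exposure_null = list(method = "uniform_time", n_sim = 2000),
      qc_sd_threshold = 4
    )
  )
}

#' Run the simulation-to-statistics pipeline
#'
#' Executes the requested stages in order on one seeded run:
#' \describe{
#'   \item{simulate}{builds every cohort from the configuration and writes
#'     JSONL event logs;}
#'   \item{extract}{reconstructs decisions, latencies, condition means,
#'     catch rates and performance QC, written as CSV;}
#'   \item{effects}{fits the control-only condition-effects LME per cohort
#'     and the per-subject summary statistics;}
#'   \item{dissociate}{ranks each lesion agent within its own control group
#'     and runs the ordinal bootstrap dissociation tests between lesion
#'     groups;}
#'   \item{exposure}{pools exposure times per group, builds the token
#'     independence null, runs the KS tests and fits all mixture variants
#'     with BIC/LBF comparison.}
#' }
#' Later stages require the artifacts of earlier ones from the same
#' `out_dir` (in-memory when run in one call, re-read from disk otherwise).
#'
#' @param config A configuration list (see [default_pipeline_config()]) or a
#'   path to a YAML file with the same structure.
#' @param out_dir Output directory; created if missing.
#' @param seed Master seed; every cohort and analysis stage derives its
#'   stream from it.
#' @param stages Character subset of
#'   `c("simulate", "extract", "effects", "dissociate", "exposure")`.
#' @return The run manifest (also written to `out_dir/manifest.json`):
#'   config hash, seed, per-stage outputs.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir, seed = 1L,
                         stages = c("simulate", "extract", "effects",
                                    "dissociate", "exposure")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- do.call(task_config, config$task)
  an <- config$analysis
  if (is.null(an)) an <- default_pipeline_config()$analysis
  manifest <- list(config_hash = config_hash(config),
                   task_config_hash = config_hash(cfg),
                   master_seed = seed,
                   started = format(Sys.time(), tz = "UTC"),
                   stages = list())
  cohort_names <- names(config$cohorts)
  cohort_seeds <- with_seed(seed,
                            sample.int(.Machine$integer.max,
                                       length(cohort_names) + 8L))
  names(cohort_seeds) <- c(cohort_names,
                           paste0("stage_", seq_len(8L)))

  cohorts <- NULL
  log_dir <- file.path(out_dir, "logs")

  if ("simulate" %in% stages) {
    cohorts <- list()
    for (cn in cohort_names) {
      cc <- config$cohorts[[cn]]
      spec <- cohort_spec(n_controls = cc$n_controls,
                          patients = cc$patients,
                          master_seed = cohort_seeds[[cn]])
      coh <- simulate_cohort(spec, cfg,
                             include_task2 = isTRUE(cc$include_task2))
      cohorts[[cn]] <- coh
      d <- file.path(log_dir, cn)
      dir.create(d, showWarnings = FALSE, recursive = TRUE)
      for (sid in names(coh$logs)) {
        for (log in coh$logs[[sid]]) {
          write_event_log(log, file.path(d, sprintf("%s_b%d.jsonl", sid,
                                                    attr(log, "block_id"))))
        }
      }
      utils::write.csv(coh$manifest,
                       file.path(d, "subjects.csv"), row.names = FALSE)
    }
    manifest$stages$simulate <- list(dir = log_dir,
                                     cohorts = cohort_names)
  }

  load_cohorts <- function() {
    if (!is.null(cohorts)) return(cohorts)
    if (!dir.exists(log_dir)) {
      stop("stage needs simulated logs; run the 'simulate' stage first or point out_dir at an existing run",
           call. = FALSE)
    }
    out <- list()
    for (cn in cohort_names) {
      d <- file.path(log_dir, cn)
      man <- utils::read.csv(file.path(d, "subjects.csv"),
                             stringsAsFactors = FALSE)
      logs <- lapply(man$subject_id, function(sid) {
        files <- sort(list.files(d, pattern = paste0("^", sid, "_b\\d+\\.jsonl$"),
                                 full.names = TRUE))
        lapply(files, read_event_log)
      })
      names(logs) <- man$subject_id
      out[[cn]] <- list(logs = logs, manifest = man)
    }
    out
  }

  task1_logs <- function(subject_logs) {
    Filter(function(l) identical(attr(l, "task"), "task1"), subject_logs)
  }
  task2_logs <- function(subject_logs) {
    Filter(function(l) identical(attr(l, "task"), "task2"), subject_logs)
  }

  tables <- NULL
  if (any(c("extract", "effects", "dissociate") %in% stages)) {
    cohorts <- load_cohorts()
    tables <- list()
    for (cn in cohort_names) {
      coh <- cohorts[[cn]]
      dec <- do.call(rbind, unlist(lapply(names(coh$logs), function(sid) {
        lapply(task1_logs(coh$logs[[sid]]), reconstruct_decisions)
      }), recursive = FALSE))
      lat <- do.call(rbind, unlist(lapply(names(coh$logs), function(sid) {
        lapply(task1_logs(coh$logs[[sid]]), function(l)
          extract_latencies(l, cfg))
      }), recursive = FALSE))
      cm <- condition_means(dec)
      grp <- coh$manifest$group[match(cm$subject_id, coh$manifest$subject_id)]
      cm$group <- ifelse(grp == "control", "control", "patient")
      perf <- vapply(names(coh$logs), function(sid)
        approach_survival_count(task1_logs(coh$logs[[sid]])), numeric(1))
      is_ctrl <- coh$manifest$group[match(names(perf),
                                          coh$manifest$subject_id)] == "control"
      qc <- performance_qc(perf[is_ctrl],
                           sd_threshold = an$qc_sd_threshold %||% 4)
      rates <- do.call(rbind, lapply(names(coh$logs), function(sid) {
        logs1 <- task1_logs(coh$logs[[sid]])
        agg <- do.call(rbind, lapply(logs1, true_catch_rates))
        out <- stats::aggregate(cbind(excursions, catches) ~ subject_id +
                                  threat_level, agg, sum)
        out$rate <- ifelse(out$excursions > 0,
                           100 * out$catches / out$excursions, NA_real_)
        out
      }))
      tables[[cn]] <- list(decisions = dec, latencies = lat,
                           condition_means = cm, performance = perf,
                           qc = qc, catch_rates = rates)
    }
    if ("extract" %in% stages) {
      ed <- file.path(out_dir, "tables")
      dir.create(ed, showWarnings = FALSE)
      for (cn in cohort_names) {
        for (tn in c("decisions", "latencies", "condition_means",
                     "catch_rates")) {
          utils::write.csv(tables[[cn]][[tn]],
                           file.path(ed, sprintf("%s_%s.csv", cn, tn)),
                           row.names = FALSE)
        }
        jsonlite::write_json(tables[[cn]]$qc,
                             file.path(ed, sprintf("%s_qc.json", cn)),
                             auto_unbox = TRUE, digits = NA)
      }
      manifest$stages$extract <- list(dir = ed)
    }
  }

  summaries <- NULL
  if (any(c("effects", "dissociate") %in% stages)) {
    summaries <- list()
    effects <- list()
    for (cn in cohort_names) {
      cm <- tables[[cn]]$condition_means
      ctrl_ids <- cohorts[[cn]]$manifest$subject_id[
        cohorts[[cn]]$manifest$group == "control"]
      ctrl_ids <- intersect(ctrl_ids, tables[[cn]]$qc$kept)
      lme <- fit_condition_lme(cm[cm$subject_id %in% ctrl_ids, ],
                               outcome = "approach_proportion")
      ss <- subject_summary(cm, an$summary_statistic %||%
                              "loss_linear_coefficient")
      summaries[[cn]] <- list(lme = lme, subject = ss, controls = ctrl_ids)
      effects[[cn]] <- lme$anova
    }
    if ("effects" %in% stages) {
      ed <- file.path(out_dir, "effects")
      dir.create(ed, showWarnings = FALSE)
      for (cn in cohort_names) {
        utils::write.csv(summaries[[cn]]$lme$anova,
                         file.path(ed, sprintf("%s_lme.csv", cn)),
                         row.names = FALSE)
        utils::write.csv(summaries[[cn]]$lme$contrasts,
                         file.path(ed, sprintf("%s_contrasts.csv", cn)),
                         row.names = FALSE)
        utils::write.csv(summaries[[cn]]$subject,
                         file.path(ed, sprintf("%s_subject_summary.csv", cn)),
                         row.names = FALSE)
      }
      manifest$stages$effects <- list(dir = ed)
    }
  }

  if ("dissociate" %in% stages) {
    ranks <- list()
    for (cn in cohort_names) {
      ss <- summaries[[cn]]$subject
      ctrl <- ss$value[ss$subject_id %in% summaries[[cn]]$controls]
      pat_ids <- cohorts[[cn]]$manifest$subject_id[
        cohorts[[cn]]$manifest$group != "control"]
      ranks[[cn]] <- lapply(pat_ids, function(pid) {
        percentile_rank(ss$value[ss$subject_id == pid], ctrl)
      })
      names(ranks[[cn]]) <- pat_ids
    }
    n_ctrl <- function(cn) length(summaries[[cn]]$controls)
    diss <- list()
    pairs <- utils::combn(cohort_names, 2, simplify = FALSE)
    k <- 0L
    for (pr in pairs) {
      k <- k + 1L
      a <- pr[1]; b <- pr[2]
      res <- ordinal_dissociation_test(
        ranks[[a]], rep(n_ctrl(a), length(ranks[[a]])),
        ranks[[b]], rep(n_ctrl(b), length(ranks[[b]])),
        n_sim = an$dissociation$n_sim %||% 10000,
        sidedness = an$dissociation$sidedness %||% "one",
        seed = cohort_seeds[["stage_1"]] + k)
      diss[[paste(a, "vs", b)]] <- res
    }
    dd <- file.path(out_dir, "dissociation")
    dir.create(dd, showWarnings = FALSE)
    rank_tab <- do.call(rbind, lapply(cohort_names, function(cn) {
      data.frame(cohort = cn, patient = names(ranks[[cn]]),
                 rank_pct = vapply(ranks[[cn]], `[[`, numeric(1), "rank_pct"),
                 n_controls = n_ctrl(cn), stringsAsFactors = FALSE)
    }))
    utils::write.csv(rank_tab, file.path(dd, "patient_ranks.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(diss, function(d) {
        list(observed_diff = d$observed_diff, p = d$p,
             sidedness = d$sidedness, n_sim = d$n_sim)
      }),
      file.path(dd, "dissociation_tests.json"), auto_unbox = TRUE,
      digits = NA)
    manifest$stages$dissociate <- list(dir = dd)
  }

  if ("exposure" %in% stages) {
    cohorts <- load_cohorts()
    t2_groups <- list(control = numeric(0), patient = numeric(0))
    sets <- list(control = list(), patient = list())
    for (cn in cohort_names) {
      if (!isTRUE(config$cohorts[[cn]]$include_task2)) next
      coh <- cohorts[[cn]]
      for (sid in names(coh$logs)) {
        l2 <- task2_logs(coh$logs[[sid]])
        if (length(l2) == 0) next
        el <- exposure_latencies(l2)
        grp <- if (coh$manifest$group[match(sid, coh$manifest$subject_id)] ==
                   "control") "control" else "patient"
        sets[[grp]] <- c(sets[[grp]], list(el))
        t2_groups[[grp]] <- c(t2_groups[[grp]], el$t2)
      }
    }
    if (length(t2_groups$control) == 0) {
      stop("exposure stage requires at least one cohort with include_task2",
           call. = FALSE)
    }
    null <- build_null_distribution(cfg,
                                    method = an$exposure_null$method %||%
                                      "uniform_time",
                                    n_sim = an$exposure_null$n_sim %||% 2000,
                                    seed = cohort_seeds[["stage_2"]])
    two_groups <- length(t2_groups$patient) > 0
    ks <- ks_exposure_tests(sets$control,
                            if (two_groups) sets$patient else NULL, null)
    groups <- if (two_groups) t2_groups else t2_groups["control"]
    variants <- if (two_groups) {
      c("combined", "split_lambda", "split_mu", "split_sigma", "split_w",
        "split_lambda_w")
    } else "combined"
    fits <- lapply(variants, function(v) {
      fit_exposure_mixture(groups, null, v,
                           seed = cohort_seeds[["stage_3"]])
    })
    cmp <- compare_exposure_models(fits)
    xd <- file.path(out_dir, "exposure")
    dir.create(xd, showWarnings = FALSE)
    utils::write.csv(as.data.frame(cmp), file.path(xd, "model_comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(best = attr(cmp, "best"), decisive = attr(cmp, "decisive"),
           ks_one_sample_p = lapply(ks$one_sample, function(k) k$p.value),
           fits = lapply(fits, function(f) {
             list(variant = f$variant, parameters = f$parameters,
                  log_likelihood = f$log_likelihood, bic = f$bic,
                  n_obs = f$n_obs, flags = f$flags)
           })),
      file.path(xd, "exposure_fits.json"), auto_unbox = TRUE, digits = NA)
    manifest$stages$exposure <- list(dir = xd, best = attr(cmp, "best"))
  }

  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
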