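#' Greenhouse-Geisser epsilon
#'
#' Sphericity correction factor estimated from the sample covariance of
#' within-subject condition means. With orthonormal effect contrasts `C`
#' (rows spanning the effect space) and condition covariance `S`, the
#' estimator is `tr(CSC')^2 / (q * tr((CSC')^2))` with `q = nrow(C)`,
#' clipped to `[1/q, 1]`. The default contrasts span all `k - 1` differences
#' among the columns of `m`, giving the usual one-way repeated-measures
#' epsilon with lower bound `1/(k - 1)`.
#'
#' @param m Numeric matrix, subjects in rows, conditions in columns
#'   (`n >= 2` rows, `k >= 2` columns).
#' @param contrasts Optional `q x k` matrix of effect contrasts (rows summing
#'   to zero); orthonormalized internally.
#' @return Epsilon in `[1/q, 1]`.
#' @examples
#' m <- matrix(rnorm(40), 10, 4)
#' gg_epsilon(m)
#' @export
gg_epsilon <- function(m, contrasts = NULL) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 conditions",
                           call. = FALSE)
  if (is.null(contrasts)) contrasts <- t(stats::contr.helmert(k))
  C <- orthonormalize_rows(contrasts)
  q <- nrow(C)
  S <- stats::cov(m)
  E <- C %*% S %*% t(C)
  tr <- sum(diag(E))
  denom <- q * sum(E * E)
  eps <- if (denom > 0) tr^2 / denom else 1
  min(max(eps, 1 / q), 1)
}

orthonormalize_rows <- function(C) {
  # Gram-Schmidt on the rows
  C <- as.matrix(C)
  out <- matrix(0, nrow(C), ncol(C))
  r <- 0L
  for (i in seq_len(nrow(C))) {
    v <- C[i, ]
    if (r > 0) v <- v - t(out[seq_len(r), , drop = FALSE]) %*%
        (out[seq_len(r), , drop = FALSE] %*% v)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-10) {
      r <- r + 1L
      out[r, ] <- v / nv
    }
  }
  out[seq_len(r), , drop = FALSE]
}

# interaction contrasts for a threat x loss cell grid, cells ordered
# loss-within-threat
interaction_contrasts <- function(k1, k2) {
  C1 <- t(stats::contr.helmert(k1))
  C2 <- t(stats::contr.helmert(k2))
  kronecker(C1, C2)
}

#' Fit the condition-effects linear mixed model
#'
#' The group-level analysis of the approach-avoidance readouts: outcome
#' modelled on threat level x potential loss (x group, when a `group` column
#' is present) as crossed fixed factors with a random subject intercept and a
#' single un-partitioned residual variance. F tests use the Satterthwaite
#' approximation to denominator degrees of freedom (delegated to
#' \pkg{lmerTest}). For the approach-proportion outcome, which enters as 18
#' condition means per subject, p values are additionally Greenhouse-Geisser
#' corrected: both degrees of freedom of each within-subject F test are
#' multiplied by the effect's epsilon estimated from the subject-by-condition
#' means. A companion model with numeric threat (-1, 0, 1) and loss codes
#' supplies the linear-contrast rows.
#'
#' @param data For `outcome = "approach_proportion"`, a condition-means table
#'   from [condition_means()]; for the latency outcomes, a single-trial
#'   table from [extract_latencies()] (sixth token already excluded). May
#'   contain rows from several subjects and an optional `group` column.
#' @param outcome One of "approach_proportion", "approach_latency",
#'   "return_latency".
#' @param covariates Optional character vector of additional numeric
#'   covariate columns, entered crossed with the within-subject factors.
#' @return An object of class `condition_lme` with elements `anova`
#'   (effect, F, df1, df2, epsilon, p, p_gg), `contrasts` (linear-contrast
#'   rows with Satterthwaite t tests), `model`, `singular`, `outcome`.
#' @export
fit_condition_lme <- function(data,
                              outcome = c("approach_proportion",
                                          "approach_latency",
                                          "return_latency"),
                              covariates = NULL) {
  outcome <- match.arg(outcome)
  value_col <- switch(outcome,
                      approach_proportion = "approach_proportion",
                      approach_latency = "approach_latency_ms",
                      return_latency = "return_latency_ms")
  d <- as.data.frame(data)
  if (!value_col %in% names(d)) {
    stop(sprintf("column '%s' not found in `data`", value_col), call. = FALSE)
  }
  d$.value <- d[[value_col]]
  d <- d[is.finite(d$.value), , drop = FALSE]
  if (length(unique(d$subject_id)) < 2) {
    stop("need >= 2 subjects to fit the mixed model", call. = FALSE)
  }
  d$subject <- factor(d$subject_id)
  d$threat_f <- factor(d$threat_level, levels = threat_levels())
  d$loss_f <- factor(d$potential_loss)
  d$threat_n <- threat_code(d$threat_level)
  d$loss_n <- as.numeric(d$potential_loss)
  has_group <- "group" %in% names(d) && length(unique(d$group)) > 1
  if (has_group) d$group_f <- factor(d$group)

  fixed <- if (has_group) "group_f * threat_f * loss_f" else
    "threat_f * loss_f"
  if (!is.null(covariates)) {
    within <- if (has_group) "threat_f * loss_f" else fixed
    fixed <- paste(fixed, paste(sprintf("%s * (%s)", covariates, within),
                                collapse = " + "), sep = " + ")
  }
  fml <- stats::as.formula(paste(".value ~", fixed, "+ (1 | subject)"))
  contr <- list(threat_f = "contr.sum", loss_f = "contr.sum")
  if (has_group) contr$group_f <- "contr.sum"
  fit <- lmerTest::lmer(fml, data = d, contrasts = contr)
  singular <- lme4::isSingular(fit)
  at <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  tab <- data.frame(effect = rownames(at),
                    F = at[["F value"]],
                    df1 = at[["NumDF"]], df2 = at[["DenDF"]],
                    epsilon = NA_real_,
                    p = stats::pf(at[["F value"]], at[["NumDF"]],
                                  at[["DenDF"]], lower.tail = FALSE),
                    stringsAsFactors = FALSE)

  if (outcome == "approach_proportion") {
    eps <- effect_epsilons(d)
    for (i in seq_len(nrow(tab))) {
      eff <- tab$effect[i]
      has_t <- grepl("threat_f", eff)
      has_l <- grepl("loss_f", eff)
      e <- if (has_t && has_l) eps["interaction"] else
        if (has_t) eps["threat"] else if (has_l) eps["loss"] else NA_real_
      tab$epsilon[i] <- e
    }
    tab$p_gg <- ifelse(is.na(tab$epsilon), tab$p,
                       stats::pf(tab$F, tab$epsilon * tab$df1,
                                 tab$epsilon * tab$df2, lower.tail = FALSE))
  } else {
    tab$p_gg <- tab$p
  }

  lin_fixed <- if (has_group) "group_f * threat_n * loss_n" else
    "threat_n * loss_n"
  lin_fml <- stats::as.formula(paste(".value ~", lin_fixed, "+ (1 | subject)"))
  lin_fit <- lmerTest::lmer(lin_fml, data = d,
                            contrasts = if (has_group)
                              list(group_f = "contr.sum") else NULL)
  sc <- stats::coef(summary(lin_fit))
  keep <- rownames(sc) != "(Intercept)"
  contrasts_tab <- data.frame(term = rownames(sc)[keep],
                              estimate = sc[keep, "Estimate"],
                              se = sc[keep, "Std. Error"],
                              df = sc[keep, "df"],
                              t = sc[keep, "t value"],
                              p = sc[keep, "Pr(>|t|)"],
                              stringsAsFactors = FALSE,
                              row.names = NULL)

  structure(list(anova = tab, contrasts = contrasts_tab, model = fit,
                 linear_model = lin_fit, singular = singular,
                 outcome = outcome, n_subjects = nlevels(d$subject)),
            class = "condition_lme")
}

# per-effect GG epsilons from subject x cell means (controls and patients
# pooled; within-subject covariance only)
effect_epsilons <- function(d) {
  subjects <- levels(d$subject)
  t_lev <- levels(d$threat_f)
  l_lev <- levels(d$loss_f)
  cell_mean <- function(s, tl = NULL, ll = NULL) {
    sel <- d$subject == s
    if (!is.null(tl)) sel <- sel & d$threat_f == tl
    if (!is.null(ll)) sel <- sel & d$loss_f == ll
    if (!any(sel)) NA_real_ else mean(d$.value[sel])
  }
  mt <- t(vapply(subjects, function(s)
    vapply(t_lev, function(tl) cell_mean(s, tl = tl), numeric(1)),
    numeric(length(t_lev))))
  ml <- t(vapply(subjects, function(s)
    vapply(l_lev, function(ll) cell_mean(s, ll = ll), numeric(1)),
    numeric(length(l_lev))))
  # 18 cells ordered loss-within-threat to match kronecker(C_threat, C_loss)
  grid <- expand.grid(loss = l_lev, threat = t_lev,
                      stringsAsFactors = FALSE)[, c("threat", "loss")]
  mc <- t(vapply(subjects, function(s)
    mapply(function(tl, ll) cell_mean(s, tl, ll), grid$threat, grid$loss),
    numeric(nrow(grid))))
  safe_eps <- function(m, contrasts = NULL) {
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) < 2) return(NA_real_)
    gg_epsilon(m, contrasts)
  }
  c(threat = safe_eps(mt),
    loss = safe_eps(ml),
    interaction = safe_eps(mc, interaction_contrasts(length(t_lev),
                                                     length(l_lev))))
}

#' @export
print.condition_lme <- function(x, digits = 3, ...) {
  cat(sprintf("Condition-effects LME (%s, %d subjects%s)\n", x$outcome,
              x$n_subjects,
              if (x$singular) "; singular fit - interpret with care" else ""))
  tab <- x$anova
  tab$F <- round(tab$F, digits); tab$df2 <- round(tab$df2, 1)
  tab$epsilon <- round(tab$epsilon, digits)
  tab$p <- signif(tab$p, digits); tab$p_gg <- signif(tab$p_gg, digits)
  print(tab, row.names = FALSE)
  cat("Linear contrasts:\n")
  ct <- x$contrasts
  ct$estimate <- signif(ct$estimate, digits); ct$se <- signif(ct$se, digits)
  ct$df <- round(ct$df, 1); ct$t <- round(ct$t, digits)
  ct$p <- signif(ct$p, digits)
  print(ct, row.names = FALSE)
  invisible(x)
}

#' Per-subject summary statistics
#'
#' The single-subject statistics that feed the single-case rank analysis:
#' the least-squares slope of the subject's condition means on potential
#' loss (averaged over threat levels), the slope on the threat code (-1, 0,
#' 1, averaged over loss), or the overall mean of included values.
#'
#' @param data A condition-means or latency table (as in
#'   [fit_condition_lme()]).
#' @param statistic One of "loss_linear_coefficient",
#'   "threat_linear_coefficient", "overall_mean".
#' @param value_col Column holding the outcome; guessed from the table when
#'   missing.
#' @return Data frame with columns `subject_id`, `statistic`, `value`.
#' @examples
#' d <- data.frame(subject_id = "s1", threat_level = "med",
#'                 potential_loss = 0:5,
#'                 approach_proportion = seq(1, 0, by = -0.2))
#' subject_summary(d, "loss_linear_coefficient")
#' @export
subject_summary <- function(data,
                            statistic = c("loss_linear_coefficient",
                                          "threat_linear_coefficient",
                                          "overall_mean"),
                            value_col = NULL) {
  statistic <- match.arg(statistic)
  d <- as.data.frame(data)
  if (is.null(value_col)) {
    value_col <- intersect(c("approach_proportion", "approach_latency_ms",
                             "return_latency_ms", "value"), names(d))[1]
    if (is.na(value_col)) stop("cannot guess `value_col`", call. = FALSE)
  }
  d$.value <- d[[value_col]]
  d <- d[is.finite(d$.value), , drop = FALSE]
  per_subject <- split(d, d$subject_id)
  vals <- vapply(per_subject, function(s) {
    switch(statistic,
           overall_mean = mean(s$.value),
           loss_linear_coefficient = {
             m <- stats::aggregate(.value ~ potential_loss, s, mean)
             if (nrow(m) < 2) return(NA_real_)
             unname(stats::coef(stats::lm(.value ~ potential_loss, m))[2])
           },
           threat_linear_coefficient = {
             s$tc <- threat_code(s$threat_level)
             m <- stats::aggregate(.value ~ tc, s, mean)
             if (nrow(m) < 2) return(NA_real_)
             unname(stats::coef(stats::lm(.value ~ tc, m))[2])
           })
  }, numeric(1))
  data.frame(subject_id = names(per_subject), statistic = statistic,
             value = unname(vals), stringsAsFactors = FALSE)
}
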