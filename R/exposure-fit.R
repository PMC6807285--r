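#' Mixture model of exposure times
#'
#' Maximum-likelihood fit of the two-process exposure-time model: each
#' press-to-last-token latency `T2` arises with probability `w` from a
#' token-unrelated process whose density is the empirical null (presses
#' spread evenly over the epoch), and with probability `1 - w` from a simple
#' reaction to the token, modelled as an exGauss with Gaussian location `mu`
#' and SD `sigma` and exponential rate `lam`:
#' `p(t) = w * f_null(t) + (1 - w) * f_exG(t; mu, sigma, lam)`.
#' Both components are renormalized over the observed latency window so the
#' likelihood is proper under truncation.
#'
#' Model variants share or split parameters between groups: `"combined"`
#' shares all four; `"split_lambda"`, `"split_mu"`, `"split_sigma"`,
#' `"split_w"` give that one parameter a group-specific value;
#' `"split_lambda_w"` splits both `lam` and `w`. Optimization runs from
#' `n_starts` moment-based starting points with seeded jitter, on
#' unconstrained scales (logit `w`, log `sigma`, log `lam`).
#'
#' @param t2_by_group Named list of numeric `T2` vectors (ms), one per
#'   group; a single unnamed vector is treated as one group.
#' @param null An `exposure_null` from [build_null_distribution()].
#' @param variant Parameter-sharing variant, see Details.
#' @param n_starts Number of optimizer restarts (default 10).
#' @param seed Optional integer seed for the restart jitter.
#' @return An object of class `exposure_mixture_fit`: `parameters` (one row
#'   per group: `w`, `mu`, `sigma`, `lam`), `log_likelihood`, `n_obs`,
#'   `n_params`, `bic`, `variant`, `converged`, and `flags` (e.g. exGauss
#'   parameters unidentifiable when `w` sits at its upper bound).
#' @examples
#' \donttest{
#' cfg <- task_config()
#' null <- build_null_distribution(cfg, "uniform_time", n_sim = 500, seed = 1)
#' t2 <- c(rexgauss(500, 300, 80, 1 / 200),
#'         sample(null$samples, 300, replace = TRUE))
#' fit <- fit_exposure_mixture(list(all = t2), null, "combined", seed = 1)
#' coef(fit)
#' }
#' @export
fit_exposure_mixture <- function(t2_by_group, null,
                                 variant = c("combined", "split_lambda",
                                             "split_mu", "split_sigma",
                                             "split_w", "split_lambda_w"),
                                 n_starts = 10, seed = NULL) {
  variant <- match.arg(variant)
  if (!inherits(null, "exposure_null")) {
    stop("`null` must come from build_null_distribution()", call. = FALSE)
  }
  if (is.numeric(t2_by_group)) t2_by_group <- list(all = t2_by_group)
  groups <- names(t2_by_group)
  if (is.null(groups)) groups <- paste0("g", seq_along(t2_by_group))
  G <- length(t2_by_group)
  split_set <- switch(variant,
                      combined = character(0),
                      split_lambda = "lam", split_mu = "mu",
                      split_sigma = "sigma", split_w = "w",
                      split_lambda_w = c("lam", "w"))
  if (G < 2 && length(split_set) > 0) {
    stop("split variants need >= 2 groups", call. = FALSE)
  }
  x_all <- unlist(t2_by_group)
  if (any(x_all < 0)) stop("T2 latencies must be >= 0", call. = FALSE)
  w_max <- max(x_all, max(null$breaks))
  window <- c(0, w_max)

  # null component renormalized over the window (support is within it)
  fnull <- lapply(t2_by_group, function(x) pmax(null_pdf(null, x), 0))
  pnames <- c("w", "mu", "sigma", "lam")
  n_per <- ifelse(pnames %in% split_set, G, 1L)
  names(n_per) <- pnames

  unpack <- function(theta) {
    out <- matrix(NA_real_, G, 4, dimnames = list(groups, pnames))
    k <- 0L
    for (p in pnames) {
      v <- theta[k + seq_len(n_per[p])]
      k <- k + n_per[p]
      v <- switch(p, w = stats::plogis(v), mu = v, sigma = exp(v),
                  lam = exp(v))
      out[, p] <- if (n_per[p] == 1L) rep(v, G) else v
    }
    out
  }
  nll <- function(theta) {
    par <- unpack(theta)
    total <- 0
    for (g in seq_len(G)) {
      x <- t2_by_group[[g]]
      w <- par[g, "w"]; mu <- par[g, "mu"]
      sigma <- par[g, "sigma"]; lam <- par[g, "lam"]
      z <- pexgauss(window[2], mu, sigma, lam) -
        pexgauss(window[1], mu, sigma, lam)
      if (!is.finite(z) || z <= 1e-12) return(1e10)
      fex <- dexgauss(x, mu, sigma, lam) / z
      dens <- w * fnull[[g]] + (1 - w) * fex
      if (any(!is.finite(dens))) return(1e10)
      total <- total - sum(log(pmax(dens, 1e-300)))
    }
    if (!is.finite(total)) 1e10 else total
  }

  # moment-based start from the pooled data
  m <- mean(x_all); s <- stats::sd(x_all)
  g1 <- mean((x_all - m)^3) / s^3
  tau0 <- s * (max(g1, 0.05) / 2)^(1 / 3)
  tau0 <- min(max(tau0, 10), w_max)
  mu0 <- m - tau0
  sigma0 <- sqrt(max(s^2 - tau0^2, (0.2 * s)^2))
  theta0 <- c(rep(stats::qlogis(0.3), n_per["w"]),
              rep(mu0, n_per["mu"]),
              rep(log(sigma0), n_per["sigma"]),
              rep(log(1 / tau0), n_per["lam"]))
  mu_slots <- n_per["w"] + seq_len(n_per["mu"])
  lower <- c(rep(-12, n_per["w"]), rep(-w_max, n_per["mu"]),
             rep(log(1), n_per["sigma"]), rep(log(1e-6), n_per["lam"]))
  upper <- c(rep(12, n_per["w"]), rep(w_max, n_per["mu"]),
             rep(log(10 * w_max), n_per["sigma"]), rep(log(1), n_per["lam"]))
  theta0 <- pmin(pmax(theta0, lower), upper)

  best <- NULL
  n_conv <- 0L
  with_seed(seed, {
    for (s_i in seq_len(n_starts)) {
      th <- theta0
      if (s_i > 1) {
        jit <- stats::rnorm(length(th), 0, 0.6)
        th <- th + jit
        th[mu_slots] <- theta0[mu_slots] * exp(jit[mu_slots] * 0.3)
        th <- pmin(pmax(th, lower), upper)
      }
      res <- tryCatch(
        stats::optim(th, nll, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 500)),
        error = function(e) NULL)
      if (is.null(res)) {
        res <- tryCatch(
          stats::optim(th, nll, method = "Nelder-Mead",
                       control = list(maxit = 2000)),
          error = function(e) NULL)
      }
      if (is.null(res) || !is.finite(res$value) || res$value >= 1e10) next
      if (res$convergence == 0) n_conv <- n_conv + 1L
      if (is.null(best) || res$value < best$value) best <- res
    }
  })
  if (is.null(best)) {
    stop("mixture optimization failed from every start", call. = FALSE)
  }
  par <- unpack(best$par)
  ll <- -best$value
  n_obs <- length(x_all)
  n_params <- sum(n_per)
  flags <- character(0)
  if (any(par[, "w"] > 0.99)) {
    flags <- c(flags,
               "w at upper bound: exGauss parameters unidentifiable")
  }
  if (n_conv == 0L) flags <- c(flags, "no optimizer start formally converged")
  structure(list(variant = variant,
                 parameters = as.data.frame(par),
                 log_likelihood = ll,
                 n_obs = n_obs, n_params = n_params,
                 bic = n_params * log(n_obs) - 2 * ll,
                 window = window, groups = groups,
                 converged = n_conv > 0L, flags = flags,
                 n_starts = n_starts, seed = seed),
            class = "exposure_mixture_fit")
}

#' @export
print.exposure_mixture_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Exposure-time mixture fit (%s): logLik %.2f, BIC %.2f, n = %d\n",
              x$variant, x$log_likelihood, x$bic, x$n_obs))
  print(signif(as.matrix(x$parameters), digits))
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}

#' @export
coef.exposure_mixture_fit <- function(object, ...) {
  as.matrix(object$parameters)
}

#' @export
logLik.exposure_mixture_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_params,
            nobs = object$n_obs, class = "logLik")
}

#' Compare exposure mixture model variants by BIC log Bayes factors
#'
#' Model evidence is approximated from the Bayesian information criterion,
#' `BIC = n_params * log(n_obs) - 2 * logLik`, and expressed as a log Bayes
#' factor against the reference variant, `LBF = 0.5 * (BIC_ref - BIC)`. An
#' absolute LBF difference above 3 between the best and second-best variant
#' is flagged as decisive.
#'
#' @param fits List of `exposure_mixture_fit` objects on identical data.
#' @param reference Variant name used as the LBF reference (default
#'   "combined").
#' @return An object of class `exposure_model_comparison`: data frame with
#'   variant, log_likelihood, n_params, bic, lbf, plus attributes `best` and
#'   `decisive`.
#' @export
compare_exposure_models <- function(fits, reference = "combined") {
  variants <- vapply(fits, `[[`, character(1), "variant")
  names(fits) <- variants
  if (!reference %in% variants) {
    stop(sprintf("reference variant '%s' not among the fits", reference),
         call. = FALSE)
  }
  n_obs <- vapply(fits, `[[`, numeric(1), "n_obs")
  if (length(unique(n_obs)) != 1) {
    stop("all fits must be on identical data (n_obs differs)", call. = FALSE)
  }
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  tab <- data.frame(variant = variants,
                    log_likelihood = vapply(fits, `[[`, numeric(1),
                                            "log_likelihood"),
                    n_params = vapply(fits, `[[`, numeric(1), "n_params"),
                    bic = bic,
                    lbf = 0.5 * (bic[[reference]] - bic),
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(-tab$lbf), ]
  rownames(tab) <- NULL
  decisive <- nrow(tab) >= 2 && abs(tab$lbf[1] - tab$lbf[2]) > 3
  structure(tab, best = tab$variant[1], decisive = decisive,
            reference = reference,
            class = c("exposure_model_comparison", "data.frame"))
}

#' @export
print.exposure_model_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Exposure model comparison (reference: %s)\n",
              attr(x, "reference")))
  df <- as.data.frame(x)
  df$log_likelihood <- round(df$log_likelihood, 2)
  df$bic <- round(df$bic, 2); df$lbf <- round(df$lbf, digits)
  print(df, row.names = FALSE)
  cat(sprintf("best: %s (%sdecisive at |delta LBF| > 3)\n", attr(x, "best"),
              if (attr(x, "decisive")) "" else "not "))
  invisible(x)
}
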