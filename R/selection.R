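# Model selection: BIC grids over (K, S), parametric-bootstrap absolute
# fit via the G^2 deviance, and the likelihood-ratio test of time-invariant
# measurement.

#' Log-likelihood of the saturated multinomial model
#'
#' The saturated model places a free multinomial probability on every
#' observed joint response pattern. Under item nonresponse, patterns are
#' defined over the observed entries only and fitted separately within each
#' missingness pattern (stratum), which keeps the saturated likelihood at
#' least as large as any LCPM's.
#'
#' @param data An [lcpm_data()] panel.
#' @return The saturated log-likelihood \eqn{\sum_p n_p \log(n_p / n_s)}.
#' @export
saturated_loglik <- function(data) {
  N <- dim(data$Y)[1L]
  flat <- matrix(data$Y, nrow = N)
  mask_key <- apply(is.na(flat), 1L, function(b) paste(as.integer(b), collapse = ""))
  val_key <- apply(flat, 1L, function(v) paste(ifelse(is.na(v), ".", v), collapse = ","))
  total <- 0
  for (s in unique(mask_key)) {
    rows <- mask_key == s
    n_s <- sum(rows)
    counts <- table(val_key[rows])
    total <- total + sum(counts * log(counts / n_s))
  }
  total
}

#' G-squared deviance against the saturated model
#'
#' @param fit An `"lcpm_fit"`.
#' @param data Panel to evaluate on; defaults to the fitted panel.
#' @return \eqn{G^2 = -2 (\log L_{mod} - \log L_{sat})}.
#' @export
gof_g2 <- function(fit, data = NULL) {
  if (is.null(data)) data <- fit$data
  -2 * (fit$loglik - saturated_loglik(data))
}

#' Parametric bootstrap goodness-of-fit test
#'
#' Generates `B` datasets from the fitted model (same sample size and
#' covariates, the original missingness pattern re-applied), refits the same
#' model specification on each, and computes the bootstrap p-value as the
#' proportion of replicate deviances \eqn{G^2_{(b)}} exceeding the observed
#' \eqn{G^2}. The model is considered adequate when the p-value exceeds
#' 0.05. Replicates whose refit fails are dropped; a warning is raised when
#' more than 5 percent fail.
#'
#' @param fit A converged `"lcpm_fit"`.
#' @param B Number of bootstrap replicates (default 100).
#' @param seed RNG seed.
#' @param control Control settings for the refits; defaults to the original
#'   fit's control with `n_starts = 10`.
#' @param use_fit_start If `TRUE`, each bootstrap refit starts from the
#'   fitted parameters that generated the replicate (a single deterministic
#'   start near the replicate's own maximum) instead of fresh random
#'   multi-starts; substantially faster with the same null distribution in
#'   regular problems.
#' @return List with `p_value`, `g2_obs`, `g2_boot`, `n_failed`.
#' @export
bootstrap_gof <- function(fit, B = 100L, seed = NULL,
                          control = NULL, use_fit_start = FALSE) {
  stopifnot(inherits(fit, "lcpm_fit"))
  if (is.null(control)) {
    control <- fit$control
    control$n_starts <- 10L
  }
  control$seed <- NULL
  if (!is.null(seed)) set.seed(seed)
  data <- fit$data
  g2_obs <- gof_g2(fit)
  g2_boot <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    sim <- simulate_from_params(fit$params, X = data$X, Z = data$Z,
                                N = fit$N, mask = data$observed_mask)
    res <- tryCatch(fit_lcpm(sim$data, fit$spec, control,
                             start = if (use_fit_start) fit$params else NULL),
                    error = function(e) NULL)
    if (!is.null(res))
      g2_boot[b] <- -2 * (res$loglik - saturated_loglik(sim$data))
  }
  ok <- !is.na(g2_boot)
  n_failed <- sum(!ok)
  if (n_failed > 0.05 * B)
    warning(n_failed, " of ", B, " bootstrap refits failed")
  list(p_value = mean(g2_boot[ok] > g2_obs), g2_obs = g2_obs,
       g2_boot = g2_boot[ok], n_failed = n_failed)
}

#' BIC grid over numbers of classes and profiles
#'
#' Fits covariate-free LCPMs (the marginalization property lets the numbers
#' of classes and profiles be chosen without covariate effects) over a grid
#' of `(K, S)` values and tabulates their BICs, classes in rows and profiles
#' in columns. The smallest-BIC model is reported; when `bootstrap = TRUE`
#' candidates are screened in BIC order by the parametric bootstrap and the
#' first one with p-value above `boot_level` is chosen. When the panel
#' carries covariates the chosen model is refitted with them.
#'
#' @param data An [lcpm_data()] panel.
#' @param K_range,S_range Integer vectors of candidate class and profile
#'   counts.
#' @param control An [lcpm_control()] for the grid fits.
#' @param rho_time_invariant Constraint used for all grid cells.
#' @param bootstrap Screen candidates with [bootstrap_gof()]?
#' @param B,boot_level Bootstrap replicates and decision level.
#' @param refit_covariates Refit the chosen model with the panel's
#'   covariates (default `TRUE` when the panel has any)?
#' @return An object of class `"lcpm_selection"`: the BIC matrix, a
#'   long-format grid table (with convergence and identifiability flags),
#'   the chosen `(K, S)` and its fit.
#' @export
select_lcpm <- function(data, K_range = 2:6, S_range = 2:6,
                        control = lcpm_control(), rho_time_invariant = TRUE,
                        bootstrap = FALSE, B = 100L, boot_level = 0.05,
                        refit_covariates = TRUE) {
  stopifnot(length(K_range) >= 1L, length(S_range) >= 1L)
  bare <- strip_covariates(data)
  M <- dim(data$Y)[3L]
  r <- vapply(seq_len(M), function(m) max(data$Y[, , m], na.rm = TRUE), 0L)
  r <- pmax(as.integer(r), 2L)
  bic_mat <- matrix(NA_real_, length(K_range), length(S_range),
                    dimnames = list(Class = K_range, Profile = S_range))
  grid <- list()
  fits <- list()
  for (i in seq_along(K_range)) for (j in seq_along(S_range)) {
    sp <- lcpm_spec(K = K_range[i], S = S_range[j], T = dim(data$Y)[2L],
                    M = M, r = r, rho_time_invariant = rho_time_invariant)
    f <- fit_lcpm(bare, sp, control)
    bic_mat[i, j] <- stats::BIC(f)
    grid[[length(grid) + 1L]] <- data.frame(
      K = as.integer(K_range[i]), S = as.integer(S_range[j]), loglik = f$loglik,
      n_par = attr(logLik(f), "df"), bic = bic_mat[i, j],
      converged = f$converged)
    fits[[paste(K_range[i], S_range[j])]] <- f
  }
  grid <- do.call(rbind, grid)
  ord <- order(grid$bic)
  chosen <- NULL; chosen_boot <- NULL
  if (bootstrap) {
    for (o in ord) {
      f <- fits[[paste(grid$K[o], grid$S[o])]]
      bg <- bootstrap_gof(f, B = B)
      if (bg$p_value > boot_level) { chosen <- o; chosen_boot <- bg; break }
    }
    if (is.null(chosen)) chosen <- ord[1L]
  } else chosen <- ord[1L]
  best_fit <- fits[[paste(grid$K[chosen], grid$S[chosen])]]
  has_cov <- !is.null(data$X) || !is.null(data$Z)
  if (refit_covariates && has_cov) {
    sp <- lcpm_spec(K = grid$K[chosen], S = grid$S[chosen],
                    T = dim(data$Y)[2L], M = M, r = r,
                    P = if (is.null(data$X)) 0L else ncol(data$X),
                    Q = if (is.null(data$Z)) 0L else dim(data$Z)[3L],
                    rho_time_invariant = rho_time_invariant)
    best_fit <- fit_lcpm(data, sp, control)
  }
  structure(list(bic = bic_mat, grid = grid,
                 K = grid$K[chosen], S = grid$S[chosen],
                 fit = best_fit, bootstrap = chosen_boot),
            class = "lcpm_selection")
}

#' @export
print.lcpm_selection <- function(x, ...) {
  cat("LCPM model selection (BIC; classes in rows, profiles in columns)\n")
  print(round(x$bic, 2))
  cat(sprintf("chosen model: K = %d classes, S = %d profiles\n", x$K, x$S))
  invisible(x)
}

#' Likelihood-ratio test of time-invariant measurement
#'
#' Tests the constraint \eqn{\rho_{mk|c1} = \dots = \rho_{mk|cT}} for all
#' items and categories by fitting the model with and without the
#' constraint (shared random starts) and referring
#' \eqn{-2(\ell_{con} - \ell_{unc})} to a chi-squared distribution with
#' \eqn{\sum_m (r_m - 1) K (T - 1)} degrees of freedom.
#'
#' @param data An [lcpm_data()] panel.
#' @param spec An [lcpm_spec()]; its `rho_time_invariant` flag is overridden
#'   on each side of the test.
#' @param control An [lcpm_control()]. A negative statistic beyond numerical
#'   slack flags a local-maximum failure and triggers a rerun with doubled
#'   starts.
#' @return List with `statistic`, `df`, `p_value` and the two fits.
#' @export
lrt_time_invariance <- function(data, spec, control = lcpm_control()) {
  sp_con <- spec; sp_con$rho_time_invariant <- TRUE
  sp_unc <- spec; sp_unc$rho_time_invariant <- FALSE
  df <- sum(spec$r - 1L) * spec$K * (spec$T - 1L)
  attempt <- function(ctrl) {
    f_con <- fit_lcpm(data, sp_con, ctrl)
    f_unc <- fit_lcpm(data, sp_unc, ctrl)
    list(con = f_con, unc = f_unc,
         lr = -2 * (f_con$loglik - f_unc$loglik))
  }
  res <- attempt(control)
  if (res$lr < -1e-4) {
    warning("negative LR statistic: likely local maximum; retrying with ",
            "doubled starts")
    ctrl2 <- control
    ctrl2$n_starts <- 2L * control$n_starts
    res <- attempt(ctrl2)
  }
  lr <- max(res$lr, 0)
  list(statistic = lr, df = df,
       p_value = if (df > 0L) stats::pchisq(lr, df, lower.tail = FALSE) else 1,
       fit_constrained = res$con, fit_unconstrained = res$unc)
}
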