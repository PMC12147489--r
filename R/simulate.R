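# Synthetic-data generation, scenario presets, label-switching alignment
# and the parameter-recovery / classification-accuracy study drivers.

# All permutations of 1..n (n <= 6 in practice).
.perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .perms(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  dimnames(out) <- NULL
  out
}

#' Simulation scenario presets
#'
#' Builds the benchmark generating model: two latent classes, two profiles,
#' three time periods, four binary items, one baseline covariate
#' \eqn{x_i \sim N(1, 1)} and one time-dependent covariate
#' \eqn{z_{it} \sim N(1, 1)}. The `"strong"` preset uses well-separated
#' item-response probabilities (0.9 / 0.1 on every item); the `"mixed"`
#' preset moves items 3 and 4 to 0.7 / 0.3 so the classes overlap. In both,
#' the class-2 logits are \eqn{1 + (\log 9 - 1) z} under profile 1 and
#' \eqn{-1 + (\log(1/9) + 1) z} under profile 2 at every time point (so the
#' class-2 probability at the covariate mean z = 1 is 0.9 and 0.1
#' respectively), and the profile-2 logit is \eqn{-1 + x}.
#'
#' @param name `"strong"` or `"mixed"`.
#' @param N Sample size (default 500).
#' @param misspecified If `TRUE` the generated class logits additionally
#'   include a quadratic covariate term with coefficient half the linear
#'   slope; analysis models remain first-order, emulating a misspecified
#'   structural model.
#' @return An object of class `"lcpm_scenario"` with fields `spec`,
#'   `true_params`, `N`, `misspecified`.
#' @export
lcpm_scenario <- function(name = c("strong", "mixed"), N = 500L,
                          misspecified = FALSE) {
  name <- match.arg(name)
  spec <- lcpm_spec(K = 2, S = 2, T = 3, M = 4, r = 2, P = 1, Q = 1)
  rho1 <- if (name == "strong") rep(0.9, 4) else c(0.9, 0.9, 0.7, 0.7)
  rho2 <- if (name == "strong") rep(0.1, 4) else c(0.1, 0.1, 0.3, 0.3)
  rho <- array(0, dim = c(4, 2, 2))
  rho[, 1, 1] <- rho1; rho[, 2, 1] <- 1 - rho1
  rho[, 1, 2] <- rho2; rho[, 2, 2] <- 1 - rho2
  beta <- rbind(c(0, 0), c(-1, 1))
  alpha <- array(0, dim = c(3, 2, 2, 2))
  for (t in 1:3) {
    alpha[t, 1, 2, ] <- c(1, log(9) - 1)
    alpha[t, 2, 2, ] <- c(-1, log(1 / 9) + 1)
  }
  structure(list(name = name, spec = spec,
                 true_params = lcpm_params(spec, rho, beta, alpha),
                 N = as.integer(N), misspecified = isTRUE(misspecified)),
            class = "lcpm_scenario")
}

# Draw one category per row from a matrix of row-wise probabilities.
.sample_cat <- function(P) {
  n <- nrow(P); K <- ncol(P)
  cp <- P
  if (K > 1L) for (k in 2L:K) cp[, k] <- cp[, k - 1L] + P[, k]
  u <- stats::runif(n)
  if (K == 1L) return(rep(1L, n))
  as.integer(1L + rowSums(u > cp[, -K, drop = FALSE]))
}

#' Simulate a panel from explicit LCPM parameters
#'
#' @param params An [lcpm_params()] object.
#' @param X,Z Covariates to condition on (`NULL` when the spec has none).
#' @param N Number of subjects.
#' @param mask Optional logical `[N, T, M]` array; cells marked `FALSE` are
#'   set missing in the generated outcomes.
#' @param quad_coef Optional array like `alpha` giving extra quadratic-term
#'   coefficients applied to the squared time-dependent covariates during
#'   generation (used for the misspecified-model studies).
#' @return List with `data` (an [lcpm_data()]), `U` (true profiles) and
#'   `C` (`[N, T]` true classes).
#' @export
simulate_from_params <- function(params, X = NULL, Z = NULL, N,
                                 mask = NULL, quad_coef = NULL) {
  spec <- params$spec
  holder <- list(X = X, Z = Z)
  Xint <- .design_x(holder, N)
  G <- .softmax_rows(Xint %*% t(params$beta))
  U <- .sample_cat(G)
  C <- matrix(0L, N, spec$T)
  Y <- array(NA_integer_, dim = c(N, spec$T, spec$M))
  for (t in seq_len(spec$T)) {
    Zint <- .design_z(holder, t, N)
    lp <- matrix(0, N, spec$K)
    for (u in seq_len(spec$S)) {
      rows <- U == u
      if (!any(rows)) next
      A <- matrix(params$alpha[t, u, , ], nrow = spec$K)
      lp[rows, ] <- Zint[rows, , drop = FALSE] %*% t(A)
      if (!is.null(quad_coef) && spec$Q > 0L) {
        Aq <- matrix(quad_coef[t, u, , ], nrow = spec$K)
        Zsq <- Zint; Zsq[, 1L] <- 0
        Zsq[, -1L] <- Zint[, -1L, drop = FALSE]^2
        lp[rows, ] <- lp[rows, ] + Zsq[rows, , drop = FALSE] %*% t(Aq)
      }
    }
    C[, t] <- .sample_cat(.softmax_rows(lp))
    rho_t <- .rho_at(params, t)
    for (m in seq_len(spec$M)) {
      Pm <- t(rho_t[m, seq_len(spec$r[m]), , drop = FALSE][1, , ])[C[, t], , drop = FALSE]
      Y[, t, m] <- .sample_cat(Pm)
    }
  }
  if (!is.null(mask)) Y[!mask] <- NA_integer_
  list(data = lcpm_data(Y, X = X, Z = Z), U = U, C = C)
}

#' Generate a synthetic panel from a scenario
#'
#' Draws \eqn{x_i \sim N(1,1)} and \eqn{z_{it} \sim N(1,1)}, samples profile
#' memberships from \eqn{\gamma(x_i)}, class memberships from
#' \eqn{\eta^{(t)}(z_{it})} given the profile, and item responses from the
#' class-conditional multinomials. For a misspecified scenario the class
#' logits at generation include quadratic covariate terms with coefficients
#' half the linear slopes.
#'
#' @param scenario An [lcpm_scenario()].
#' @param seed RNG seed; identical scenario and seed reproduce the panel
#'   bit for bit.
#' @param prop_missing Proportion of outcome cells set missing completely
#'   at random (default 0).
#' @return An object of class `"lcpm_panel"`: list with `data`, `U`, `C`,
#'   `spec`, `scenario`.
#' @export
generate_panel <- function(scenario, seed = NULL, prop_missing = 0) {
  stopifnot(inherits(scenario, "lcpm_scenario"))
  if (!is.null(seed)) set.seed(seed)
  spec <- scenario$spec
  N <- scenario$N
  X <- matrix(stats::rnorm(N * spec$P, 1, 1), N, spec$P)
  if (spec$P == 0L) X <- NULL
  Z <- array(stats::rnorm(N * spec$T * spec$Q, 1, 1), dim = c(N, spec$T, spec$Q))
  if (spec$Q == 0L) Z <- NULL
  quad <- NULL
  if (scenario$misspecified) {
    quad <- scenario$true_params$alpha
    quad[, , , 1L] <- 0
    if (spec$Q > 0L) quad[, , , -1L] <- 0.5 * scenario$true_params$alpha[, , , -1L]
  }
  sim <- simulate_from_params(scenario$true_params, X = X, Z = Z, N = N,
                              quad_coef = quad)
  if (prop_missing > 0) {
    Y <- sim$data$Y
    drop_idx <- which(stats::runif(length(Y)) < prop_missing)
    Y[drop_idx] <- NA_integer_
    sim$data <- lcpm_data(Y, X = X, Z = Z)
  }
  structure(list(data = sim$data, U = sim$U, C = sim$C, spec = spec,
                 scenario = scenario),
            class = "lcpm_panel")
}

# Evaluate gamma and eta of a parameter set at covariates fixed at 1
# (the covariate mean in the benchmark scenarios).
.ref_probs <- function(params) {
  spec <- params$spec
  g <- profile_prevalence(rep(1, spec$P), params$beta)
  eta <- array(0, dim = c(spec$T, spec$S, spec$K))
  for (t in seq_len(spec$T)) for (u in seq_len(spec$S))
    eta[t, u, ] <- class_prevalence(rep(1, spec$Q), params$alpha, u, t)
  list(gamma = g, eta = eta)
}

#' Align class and profile labels of an estimate to a reference
#'
#' The likelihood is invariant under the \eqn{K! \times S!} permutations of
#' class and profile labels, so estimates must be aligned before they can be
#' compared to a reference parameter set. The class permutation is chosen to
#' minimize the total absolute discrepancy of the item-response
#' probabilities; the profile permutation minimizes the discrepancy of the
#' class-prevalence curves evaluated at the covariate reference point
#' (covariates = 1) together with the profile prevalences. Ties resolve to
#' the lexicographically smallest permutation. The chosen permutation is
#' applied coherently to `rho`, `beta` (re-expressed against the new
#' baseline profile), and `alpha` (re-expressed against the new baseline
#' class).
#'
#' @param estimate,truth [lcpm_params()] objects with equal `K`, `S`, `T`.
#'   (`truth` may have different covariate counts; reference probabilities
#'   are evaluated under each spec's own covariates.)
#' @return List with `params` (relabeled estimate), `perm_class`,
#'   `perm_profile`.
#' @export
align_labels <- function(estimate, truth) {
  se <- estimate$spec; st <- truth$spec
  stopifnot(se$K == st$K, se$S == st$S, se$T == st$T, se$M == st$M)
  K <- se$K; S <- se$S
  ref_t <- .ref_probs(truth)
  ref_e <- .ref_probs(estimate)
  rho_e <- estimate$rho; rho_t <- truth$rho
  best <- NULL; best_d <- Inf
  pc_all <- .perms(K); pu_all <- .perms(S)
  for (ic in seq_len(nrow(pc_all))) {
    pc <- pc_all[ic, ]
    d_rho <- sum(abs(rho_e[, , pc, 1L, drop = FALSE] -
                     rho_t[, , , 1L, drop = FALSE]))
    for (iu in seq_len(nrow(pu_all))) {
      pu <- pu_all[iu, ]
      d_eta <- sum(abs(ref_e$eta[, pu, pc, drop = FALSE] - ref_t$eta)) +
        sum(abs(ref_e$gamma[pu] - ref_t$gamma))
      d <- d_rho + d_eta
      if (d < best_d - 1e-12) {
        best_d <- d
        best <- list(pc = pc, pu = pu)
      }
    }
  }
  pc <- best$pc; pu <- best$pu
  out <- estimate
  out$rho <- estimate$rho[, , pc, , drop = FALSE]
  dim(out$rho) <- dim(estimate$rho)
  new_beta <- estimate$beta[pu, , drop = FALSE]
  new_beta <- sweep(new_beta, 2L, new_beta[1L, ])
  out$beta <- new_beta
  new_alpha <- estimate$alpha[, pu, pc, , drop = FALSE]
  dim(new_alpha) <- dim(estimate$alpha)
  for (t in seq_len(se$T)) for (u in seq_len(S)) {
    a <- matrix(new_alpha[t, u, , ], nrow = K)
    a <- sweep(a, 2L, a[1L, ])
    new_alpha[t, u, , ] <- a
  }
  out$alpha <- new_alpha
  list(params = out, perm_class = pc, perm_profile = pu)
}

#' Maximum-posterior membership prediction
#'
#' Assigns each subject to the latent profile and, at every time point, the
#' latent class with the highest posterior probability (ties go to the
#' lowest index).
#'
#' @param params Fitted [lcpm_params()].
#' @param data Panel of subjects to classify.
#' @return List with `U_hat` (length-N) and `C_hat` (`[N, T]`).
#' @export
predict_memberships <- function(params, data) {
  post <- e_step(params, data)
  N <- dim(data$Y)[1L]
  U_hat <- max.col(post$theta_u, ties.method = "first")
  C_hat <- matrix(0L, N, params$spec$T)
  for (t in seq_len(params$spec$T))
    C_hat[, t] <- max.col(matrix(post$theta_ct[, t, ], N, params$spec$K),
                          ties.method = "first")
  list(U_hat = U_hat, C_hat = C_hat)
}

#' Parameter-recovery simulation study
#'
#' Repeatedly generates a panel from the scenario's true parameters, fits
#' the LCPM with covariates, aligns labels to the truth, and computes
#' per-parameter point estimates and Wald intervals. Reported metrics per
#' free parameter: standardized bias (mean estimation error divided by the
#' replicate-to-replicate standard deviation of the estimates; absolute
#' values above 0.4 are conventionally unacceptable), mean 95 percent CI
#' length, root mean-squared error, and empirical coverage. Item-response
#' probabilities are assessed on the probability scale, coefficients on the
#' logit scale.
#'
#' @param scenario An [lcpm_scenario()].
#' @param n_reps Number of replicates (>= 2).
#' @param control An [lcpm_control()] for the fits.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param level Interval coverage level.
#' @return An object of class `"lcpm_recovery"`: `metrics` data.frame with
#'   columns `parameter`, `truth`, `bias_std`, `ci_length`, `rmse`,
#'   `coverage`; plus the raw `estimates` matrix and failure count.
#' @export
run_recovery_study <- function(scenario, n_reps = 500L,
                               control = lcpm_control(n_starts = 3L),
                               seed = 1L, level = 0.95) {
  stopifnot(n_reps >= 2L)
  spec <- scenario$spec
  truth <- scenario$true_params
  tab <- free_param_table(spec)
  truth_vec <- pack_params(truth)
  # rho entries are tracked on the probability scale
  is_rho <- tab$type == "rho"
  truth_nat <- truth_vec
  for (i in which(is_rho))
    truth_nat[i] <- truth$rho[tab$m[i], tab$k[i], tab$c[i], tab$t[i]]
  est <- low <- upp <- matrix(NA_real_, n_reps, nrow(tab),
                              dimnames = list(NULL, tab$name))
  n_fail <- 0L
  for (r in seq_len(n_reps)) {
    panel <- generate_panel(scenario, seed = seed + r)
    res <- tryCatch({
      fit <- fit_lcpm(panel$data, spec, control)
      al <- align_labels(fit$params, truth)
      frozen_al <- fit$boundary_flags[, al$perm_profile, al$perm_class,
                                      drop = FALSE]
      dim(frozen_al) <- dim(fit$boundary_flags)
      inf <- observed_information(al$params, data = panel$data,
                                  frozen = frozen_al)
      wt <- wald_intervals(inf, level = level)
      list(wt = wt, identifiable = inf$identifiable)
    }, error = function(e) NULL)
    if (is.null(res)) { n_fail <- n_fail + 1L; next }
    wt <- res$wt
    key <- match(tab$name, wt$parameter)
    est[r, ] <- wt$estimate[key]
    low[r, ] <- wt$lower[key]
    upp[r, ] <- wt$upper[key]
  }
  if (n_fail > 0.1 * n_reps)
    warning(n_fail, " of ", n_reps, " replicates failed")
  ok <- stats::complete.cases(est)
  metrics <- data.frame(
    parameter = tab$name, type = tab$type, truth = truth_nat,
    bias_std = NA_real_, ci_length = NA_real_, rmse = NA_real_,
    coverage = NA_real_)
  for (j in seq_len(nrow(tab))) {
    e <- est[ok, j]; l <- low[ok, j]; u <- upp[ok, j]
    tv <- truth_nat[j]
    sd_e <- stats::sd(e)
    metrics$bias_std[j] <- if (sd_e > 0) mean(e - tv) / sd_e else 0
    metrics$ci_length[j] <- mean(u - l)
    metrics$rmse[j] <- sqrt(mean((e - tv)^2))
    metrics$coverage[j] <- mean(l <= tv & tv <= u)
  }
  structure(list(metrics = metrics, estimates = est[ok, , drop = FALSE],
                 lower = low[ok, , drop = FALSE],
                 upper = upp[ok, , drop = FALSE],
                 n_reps = sum(ok), n_fail = n_fail, scenario = scenario),
            class = "lcpm_recovery")
}

#' @export
print.lcpm_recovery <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d replicates (%s scenario, N = %d)\n",
              x$n_reps, x$scenario$name, x$scenario$N))
  print(cbind(x$metrics[, c("parameter", "truth")],
              round(x$metrics[, c("bias_std", "ci_length", "rmse", "coverage")], 3)),
        row.names = FALSE)
  invisible(x)
}

#' Classification-accuracy simulation study
#'
#' Per replicate: generates a panel, splits it into equal training and
#' testing halves, fits an LCPM with time-dependent covariates and a
#' covariate-free LCPM on the training half, aligns each fit's labels to
#' the truth, classifies the testing half by maximum posterior probability,
#' and scores the fraction of correctly recovered profile and class
#' memberships. Accuracies are averaged over replicates.
#'
#' @param scenario An [lcpm_scenario()].
#' @param n_reps Number of replicates.
#' @param control An [lcpm_control()].
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return An object of class `"lcpm_accuracy"`: a table with one row per
#'   model (covariates YES / NO) and columns `profile`, `class_1..class_T`.
#' @export
run_accuracy_study <- function(scenario, n_reps = 100L,
                               control = lcpm_control(n_starts = 3L),
                               seed = 1L) {
  spec <- scenario$spec
  truth <- scenario$true_params
  spec_nocov <- lcpm_spec(K = spec$K, S = spec$S, T = spec$T, M = spec$M,
                          r = spec$r, P = 0L, Q = 0L,
                          rho_time_invariant = spec$rho_time_invariant)
  acc <- array(NA_real_, dim = c(n_reps, 2L, 1L + spec$T))
  n_fail <- 0L
  for (r in seq_len(n_reps)) {
    panel <- generate_panel(scenario, seed = seed + r)
    N <- scenario$N
    idx_train <- seq_len(N %/% 2L)
    idx_test <- setdiff(seq_len(N), idx_train)
    subset_panel <- function(idx, keep_cov) {
      lcpm_data(panel$data$Y[idx, , , drop = FALSE],
                X = if (keep_cov) panel$data$X[idx, , drop = FALSE] else NULL,
                Z = if (keep_cov) panel$data$Z[idx, , , drop = FALSE] else NULL)
    }
    res <- tryCatch({
      out <- matrix(NA_real_, 2L, 1L + spec$T)
      for (mode in 1:2) {
        with_cov <- mode == 1L
        train <- subset_panel(idx_train, with_cov)
        test <- subset_panel(idx_test, with_cov)
        sp <- if (with_cov) spec else spec_nocov
        fit <- fit_lcpm(train, sp, control)
        al <- align_labels(fit$params, truth)
        pred <- predict_memberships(al$params, test)
        out[mode, 1L] <- mean(pred$U_hat == panel$U[idx_test])
        for (t in seq_len(spec$T))
          out[mode, 1L + t] <- mean(pred$C_hat[, t] == panel$C[idx_test, t])
      }
      out
    }, error = function(e) NULL)
    if (is.null(res)) { n_fail <- n_fail + 1L; next }
    acc[r, , ] <- res
  }
  if (n_fail > 0.1 * n_reps)
    warning(n_fail, " of ", n_reps, " replicates failed")
  mean_acc <- apply(acc, c(2L, 3L), mean, na.rm = TRUE)
  table <- data.frame(covariates = c("YES", "NO"), profile = mean_acc[, 1L])
  for (t in seq_len(spec$T)) table[[paste0("class_", t)]] <- mean_acc[, 1L + t]
  structure(list(table = table, raw = acc,
                 n_reps = n_reps - n_fail, n_fail = n_fail,
                 scenario = scenario),
            class = "lcpm_accuracy")
}

#' @export
print.lcpm_accuracy <- function(x, ...) {
  cat(sprintf("Classification accuracy over %d replicates (%s scenario, N = %d%s)\n",
              x$n_reps, x$scenario$name, x$scenario$N,
              if (x$scenario$misspecified) ", misspecified" else ""))
  tab <- x$table
  tab[, -1L] <- round(tab[, -1L], 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
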