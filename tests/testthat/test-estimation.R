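test_that("rho M-step reproduces hand-computed weighted frequencies", {
  sp <- lcpm_spec(K = 1, S = 1, T = 1, M = 1, r = 2)
  Y <- array(c(1L, 2L), dim = c(2, 1, 1))
  d <- lcpm_data(Y)
  # two subjects with posterior class mass 0.5 each, responses 1 and 2
  post <- list(theta_ct = array(0.5, dim = c(2, 1, 1)))
  rho_old <- array(c(0.3, 0.7), dim = c(1, 2, 1, 1))
  rho_new <- lcprofile:::m_step_rho(d, post, sp, rho_old)
  expect_equal(rho_new[1, , 1, 1], c(0.5, 0.5))

  # hard assignment: raw within-class frequencies
  sp2 <- lcpm_spec(K = 2, S = 1, T = 1, M = 1, r = 2)
  Y2 <- array(c(1L, 1L, 2L, 1L), dim = c(4, 1, 1))
  d2 <- lcpm_data(Y2)
  theta <- array(0, dim = c(4, 1, 2))
  theta[, 1, 1] <- c(1, 1, 1, 0); theta[, 1, 2] <- c(0, 0, 0, 1)
  post2 <- list(theta_ct = theta)
  rho_old2 <- array(0.5, dim = c(1, 2, 2, 1))
  rho_new2 <- lcprofile:::m_step_rho(d2, post2, sp2, rho_old2)
  expect_equal(rho_new2[1, , 1, 1], c(2 / 3, 1 / 3))
  expect_equal(rho_new2[1, , 2, 1], c(1, 0))

  # with no missing cells the MAR correction changes nothing: the update
  # must not depend on the previous rho
  rho_other <- array(c(0.9, 0.1), dim = c(1, 2, 2, 1))
  expect_equal(lcprofile:::m_step_rho(d2, post2, sp2, rho_other), rho_new2)
})

test_that("MAR-corrected rho update fills missing mass with previous rho", {
  sp <- lcpm_spec(K = 1, S = 1, T = 1, M = 1, r = 2)
  Y <- array(c(1L, NA), dim = c(2, 1, 1))
  d <- lcpm_data(Y)
  post <- list(theta_ct = array(1, dim = c(2, 1, 1)))
  rho_old <- array(c(0.4, 0.6), dim = c(1, 2, 1, 1))
  rho_new <- lcprofile:::m_step_rho(d, post, sp, rho_old)
  # (1 + 0.4) / 2 and (0 + 0.6) / 2
  expect_equal(rho_new[1, , 1, 1], c(0.7, 0.3))
})

test_that("Newton update matches an independent multinomial-logit fit", {
  skip_if_not_installed("nnet")
  set.seed(31)
  N <- 150
  X <- matrix(rnorm(N, 1, 1), N, 1)
  sp <- lcpm_spec(K = 1, S = 2, T = 1, M = 1, r = 2, P = 1)
  # hard 0/1 profile weights drawn from a logistic truth
  p2 <- plogis(-0.5 + 0.8 * X[, 1])
  u <- 1L + (runif(N) < p2)
  theta_u <- cbind(u == 1L, u == 2L) * 1
  Y <- array(1L, dim = c(N, 1, 1))
  d <- lcpm_data(Y, X = X)
  params <- lcpm_params(sp, array(0.5, dim = c(1, 2, 1)),
                        matrix(0, 2, 2), array(0, dim = c(1, 2, 1, 1)))
  post <- list(theta_u = theta_u,
               theta_u_ct = array(theta_u, dim = c(N, 2, 1, 1)),
               theta_ct = array(1, dim = c(N, 1, 1)))
  ctrl <- lcpm_control(newton_steps_per_m = 50)
  upd <- newton_update(d, post, params, ctrl)
  ref <- nnet::multinom(factor(u) ~ X, trace = FALSE, reltol = 1e-14)
  expect_equal(unname(upd$beta[2, ]), unname(coef(ref)), tolerance = 1e-6)
  # one further Newton step from the optimum moves essentially nowhere
  upd2 <- newton_update(d, post, upd, lcpm_control(newton_steps_per_m = 1))
  expect_lt(max(abs(upd2$beta - upd$beta)), 1e-6)
})

test_that("uniform weights with zero coefficients are a stationary point", {
  set.seed(32)
  N <- 40
  X <- matrix(scale(rnorm(N), scale = FALSE), N, 1)  # centered covariate
  sp <- lcpm_spec(K = 1, S = 2, T = 1, M = 1, r = 2, P = 1)
  params <- lcpm_params(sp, array(0.5, dim = c(1, 2, 1)),
                        matrix(0, 2, 2), array(0, dim = c(1, 2, 1, 1)))
  post <- list(theta_u = matrix(0.5, N, 2),
               theta_u_ct = array(0.5, dim = c(N, 2, 1, 1)),
               theta_ct = array(1, dim = c(N, 1, 1)))
  d <- lcpm_data(array(1L, dim = c(N, 1, 1)), X = X)
  upd <- newton_update(d, post, params, lcpm_control(newton_steps_per_m = 1))
  expect_equal(upd$beta, params$beta, tolerance = 1e-10)
})

test_that("EM ascends and recovers a degenerate one-class model exactly", {
  set.seed(33)
  sp <- lcpm_spec(K = 1, S = 1, T = 2, M = 2, r = 2)
  Y <- array(sample(1:2, 40, replace = TRUE, prob = c(0.7, 0.3)),
             dim = c(10, 2, 2))
  d <- lcpm_data(Y)
  fit <- fit_lcpm(d, sp, lcpm_control(n_starts = 1, seed = 5))
  for (m in 1:2) {
    v <- Y[, , m]
    expect_equal(fit$params$rho[m, 1, 1, 1], mean(v == 1L), tolerance = 1e-9)
  }
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("EM ascent holds on random instances with and without missingness", {
  set.seed(34)
  for (rep in 1:4) {
    inst <- random_instance(N = 40, K = 2, S = 2, T = 3, M = 3,
                            miss = ifelse(rep %% 2 == 0, 0.15, 0))
    fit <- fit_lcpm(inst$data, inst$spec,
                    lcpm_control(n_starts = 2, seed = rep, max_em_iter = 300))
    expect_true(all(diff(fit$loglik_trace) > -1e-8))
  }
})

test_that("relabeled initialization reaches the same maximum likelihood", {
  set.seed(35)
  sc <- lcpm_scenario("strong", N = 150)
  panel <- generate_panel(sc, seed = 36)
  start <- sc$true_params
  # swap both class and profile labels in the starting values
  swapped <- align_labels(start, start)$params  # identity pass-through
  swapped$rho <- start$rho[, , 2:1, , drop = FALSE]
  dim(swapped$rho) <- dim(start$rho)
  swapped$alpha <- start$alpha[, 2:1, 2:1, , drop = FALSE]
  dim(swapped$alpha) <- dim(start$alpha)
  for (t in 1:3) for (u in 1:2) {
    a <- matrix(swapped$alpha[t, u, , ], nrow = 2)
    swapped$alpha[t, u, , ] <- sweep(a, 2, a[1, ])
  }
  b <- start$beta[2:1, , drop = FALSE]
  swapped$beta <- sweep(b, 2, b[1, ])
  ctrl <- lcpm_control(n_starts = 1)
  f1 <- fit_lcpm(panel$data, sc$spec, ctrl, start = start)
  f2 <- fit_lcpm(panel$data, sc$spec, ctrl, start = swapped)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("near-empty class-profile cells trigger slope freezing", {
  set.seed(37)
  sp <- lcpm_spec(K = 2, S = 2, T = 3, M = 4, r = 2, P = 1, Q = 1)
  rho <- array(0, dim = c(4, 2, 2))
  rho[, 1, 1] <- 0.9; rho[, 2, 1] <- 0.1
  rho[, 1, 2] <- 0.1; rho[, 2, 2] <- 0.9
  beta <- rbind(c(0, 0), c(0.5, 0))
  alpha <- array(0, dim = c(3, 2, 2, 2))
  alpha[, 1, 2, 1] <- 2
  alpha[, 2, 2, 1] <- -15  # class 2 never occurs inside profile 2
  truth <- lcpm_params(sp, rho, beta, alpha)
  N <- 250
  X <- matrix(rnorm(N, 1, 1), N, 1)
  Z <- array(rnorm(N * 3, 1, 1), dim = c(N, 3, 1))
  sim <- simulate_from_params(truth, X = X, Z = Z, N = N)
  fit <- fit_lcpm(sim$data, sp, lcpm_control(n_starts = 3, seed = 38))
  expect_true(any(fit$boundary_flags))
  # frozen blocks carry exactly zero slopes
  for (t in 1:3) for (u in 1:2) if (any(fit$boundary_flags[t, u, ]))
    expect_identical(unname(fit$params$alpha[t, u, , 2]), c(0, 0))
  # and are excluded from the free-parameter count
  expect_lt(attr(logLik(fit), "df"), n_parameters(sp))
})
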