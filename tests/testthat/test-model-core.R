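test_that("spec validation and pattern counting behave", {
  sp <- lcpm_spec(K = 2, S = 2, T = 3, M = 4, r = 2, P = 1, Q = 1)
  expect_s3_class(sp, "lcpm_spec")
  expect_error(lcpm_spec(K = 0, S = 1, T = 1, M = 1, r = 2), "must all be")
  expect_error(lcpm_spec(K = 1, S = 1, T = 1, M = 2, r = c(2, 1)),
               "at least 2")
  expect_identical(n_response_patterns(lcpm_spec(1, 1, 1, 4, 2)), 16)
  expect_identical(n_response_patterns(sp), 4096)
})

test_that("free-parameter accounting matches hand counts", {
  # four-class latent transition model on six binary items over six weeks:
  # 6*4 measurement + 5 transition matrices of 4x4
  ltm <- lcpm_spec(K = 4, S = 1, T = 6, M = 6, r = 2)
  expect_identical(n_parameters(ltm, family = "ltm"), 104L)
  # covariate-free LCPM: 4*1*2 rho + (2-1) gamma + 3*2*(2-1) eta
  sp <- lcpm_spec(K = 2, S = 2, T = 3, M = 4, r = 2)
  expect_identical(n_parameters(sp), 15L)
  # time-varying rho multiplies the measurement block by T
  spv <- lcpm_spec(K = 2, S = 2, T = 3, M = 4, r = 2,
                   rho_time_invariant = FALSE)
  expect_identical(n_parameters(spv), 15L + 2L * 8L)
  # frozen blocks keep intercepts only
  spc <- lcpm_spec(K = 2, S = 2, T = 3, M = 4, r = 2, P = 1, Q = 1)
  flags <- array(FALSE, dim = c(3, 2, 2))
  flags[1, 1, 2] <- TRUE
  expect_identical(n_parameters(spc, boundary_flags = flags),
                   n_parameters(spc) - 1L)
})

test_that("profile prevalence is a softmax with the documented closed forms", {
  # all-zero coefficients: uniform over profiles
  beta0 <- matrix(0, 3, 2)
  expect_equal(profile_prevalence(0.7, beta0), rep(1 / 3, 3))
  # benchmark truth: intercept -1, slope 1, x = 1 gives exactly 1/2
  beta <- rbind(c(0, 0), c(-1, 1))
  expect_equal(profile_prevalence(1, beta)[2], 0.5)
  # softmax identities: equals direct evaluation; shifting all linear
  # predictors by a constant leaves probabilities unchanged, shifting only
  # the non-baseline intercepts does not
  set.seed(1)
  b <- rbind(0, matrix(rnorm(4), 2, 2))
  x <- rnorm(1)
  p1 <- profile_prevalence(x, b)
  lp <- drop(b %*% c(1, x))
  expect_equal(p1, exp(lp) / sum(exp(lp)), tolerance = 1e-12)
  expect_equal(p1, exp(lp + 3.1) / sum(exp(lp + 3.1)), tolerance = 1e-12)
  b2 <- b; b2[-1, 1] <- b2[-1, 1] + 3.1
  expect_false(isTRUE(all.equal(p1, profile_prevalence(x, b2))))
  expect_equal(sum(p1), 1, tolerance = 1e-12)
  expect_error(profile_prevalence(NaN, beta), "non-finite")
})

test_that("class prevalence reproduces the benchmark logit values", {
  sc <- lcpm_scenario("strong")
  a <- sc$true_params$alpha
  # profile 1, t = 1, z = 1: predictor 1 + (log 9 - 1) = log 9 -> 0.9
  expect_equal(class_prevalence(1, a, u = 1, t = 1)[2], 0.9)
  # profile 2: predictor -1 + (log(1/9) + 1) = log(1/9) -> 0.1
  expect_equal(class_prevalence(1, a, u = 2, t = 1)[2], 0.1)
  # all-zero coefficients: uniform over classes
  a0 <- array(0, dim = c(2, 1, 4, 1))
  expect_equal(class_prevalence(numeric(0), a0, u = 1, t = 2), rep(0.25, 4))
})

test_that("emission log-probability sums observed items and flags zeros", {
  sc <- lcpm_scenario("strong")
  p <- sc$true_params
  # four items all responding 1 in the strong class 1: log(0.9^4)
  expect_equal(emission_logprob(rep(1L, 4), p, class = 1), log(0.9^4))
  # all items missing: empty product
  expect_identical(emission_logprob(rep(NA_integer_, 4), p, class = 1), 0)
  # a certain response contributes log(1) = 0
  sp1 <- lcpm_spec(K = 1, S = 1, T = 1, M = 1, r = 2)
  p1 <- lcpm_params(sp1, array(c(1, 0), dim = c(1, 2, 1)),
                    matrix(0, 1, 1), array(0, dim = c(1, 1, 1, 1)))
  expect_identical(emission_logprob(1L, p1, class = 1), 0)
  # a zero-probability observed response yields -Inf, not an error
  expect_identical(emission_logprob(2L, p1, class = 1), -Inf)
})

test_that("degenerate one-class model reduces to summed emissions", {
  set.seed(11)
  inst <- random_instance(N = 5, K = 1, S = 1, with_cov = FALSE, miss = 0.2)
  ll <- lcpm_loglik(inst$params, inst$data)
  direct <- sapply(seq_len(5), function(i)
    sum(sapply(seq_len(inst$spec$T), function(t)
      emission_logprob(inst$data$Y[i, t, ], inst$params, class = 1, t = t))))
  expect_equal(ll$loglik_i, direct, tolerance = 1e-10)
})

test_that("log-likelihood is additive over duplicated subjects", {
  set.seed(12)
  inst <- random_instance(N = 3, with_cov = TRUE)
  dup <- lcpm_data(inst$data$Y[rep(1:3, 2), , , drop = FALSE],
                   X = inst$data$X[rep(1:3, 2), , drop = FALSE],
                   Z = inst$data$Z[rep(1:3, 2), , , drop = FALSE])
  expect_equal(lcpm_loglik(inst$params, dup)$loglik,
               2 * lcpm_loglik(inst$params, inst$data)$loglik,
               tolerance = 1e-12)
})

test_that("zero covariate slopes collapse to the covariate-free model", {
  set.seed(13)
  inst <- random_instance(N = 6, with_cov = TRUE, miss = 0)
  p <- inst$params
  p$alpha[, , , -1] <- 0
  p$beta[, -1] <- 0
  # same intercept-only parameters expressed without covariates
  sp0 <- lcpm_spec(K = inst$spec$K, S = inst$spec$S, T = inst$spec$T,
                   M = inst$spec$M, r = inst$spec$r,
                   rho_time_invariant = inst$spec$rho_time_invariant)
  p0 <- lcpm_params(sp0, p$rho,
                    p$beta[, 1, drop = FALSE],
                    p$alpha[, , , 1, drop = FALSE])
  d0 <- lcpm_data(inst$data$Y)
  expect_equal(lcpm_loglik(p, inst$data)$loglik_i,
               lcpm_loglik(p0, d0)$loglik_i, tolerance = 1e-12)
})

test_that("parameter containers enforce their constraints", {
  sp <- lcpm_spec(K = 2, S = 2, T = 2, M = 2, r = 2, P = 1, Q = 1)
  rho <- array(0.5, dim = c(2, 2, 2))
  beta <- matrix(0, 2, 2)
  alpha <- array(0, dim = c(2, 2, 2, 2))
  expect_s3_class(lcpm_params(sp, rho, beta, alpha), "lcpm_params")
  bad_beta <- beta; bad_beta[1, 1] <- 0.2
  expect_error(lcpm_params(sp, rho, bad_beta, alpha), "baseline profile")
  bad_alpha <- alpha; bad_alpha[1, 1, 1, 2] <- 1
  expect_error(lcpm_params(sp, rho, beta, bad_alpha), "baseline class")
  bad_rho <- rho; bad_rho[1, 1, 1] <- 0.7
  expect_error(lcpm_params(sp, bad_rho, beta, alpha), "sum to 1")
})

test_that("panels reject missing covariates and off-range responses", {
  Y <- array(1L, dim = c(3, 2, 2))
  X <- matrix(c(1, NA, 3), 3, 1)
  expect_error(lcpm_data(Y, X = X), "subject\\(s\\): 2")
  sp <- lcpm_spec(K = 1, S = 1, T = 2, M = 2, r = 2)
  Ybad <- Y; Ybad[1, 1, 1] <- 5L
  expect_error(lcprofile:::validate_data(lcpm_data(Ybad), sp), "outside 1..2")
})
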