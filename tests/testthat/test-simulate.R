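test_that("scenario presets encode the benchmark truth", {
  st <- lcpm_scenario("strong")
  expect_equal(st$true_params$rho[1, 1, 1, 1], 0.9)
  expect_equal(st$true_params$alpha[1, 1, 2, ], c(1, log(9) - 1))
  expect_equal(st$true_params$alpha[2, 2, 2, ], c(-1, log(1 / 9) + 1))
  expect_equal(st$true_params$beta[2, ], c(-1, 1))
  mx <- lcpm_scenario("mixed")
  expect_equal(mx$true_params$rho[3, 1, 1, 1], 0.7)
  expect_equal(mx$true_params$rho[3, 1, 2, 1], 0.3)
  expect_equal(mx$true_params$alpha, st$true_params$alpha)
})

test_that("panel generation is seed-deterministic", {
  sc <- lcpm_scenario("strong", N = 50)
  p1 <- generate_panel(sc, seed = 81)
  p2 <- generate_panel(sc, seed = 81)
  expect_identical(p1$data$Y, p2$data$Y)
  expect_identical(p1$data$X, p2$data$X)
  expect_identical(p1$U, p2$U)
  p3 <- generate_panel(sc, seed = 82)
  expect_false(identical(p1$data$Y, p3$data$Y))
})

test_that("degenerate emission probabilities make outcomes deterministic", {
  sp <- lcpm_spec(K = 2, S = 1, T = 2, M = 2, r = 2)
  rho <- array(0, dim = c(2, 2, 2))
  rho[, 1, 1] <- 1; rho[, 2, 2] <- 1
  alpha <- array(0, dim = c(2, 1, 2, 1))
  p <- lcpm_params(sp, rho, matrix(0, 1, 1), alpha)
  set.seed(83)
  sim <- simulate_from_params(p, N = 30)
  for (t in 1:2) for (m in 1:2)
    expect_identical(sim$data$Y[, t, m], ifelse(sim$C[, t] == 1L, 1L, 2L))
})

test_that("generated panels match their generating probabilities", {
  sc <- lcpm_scenario("strong", N = 100000)
  panel <- generate_panel(sc, seed = 84)
  # P(Y_1t = 1 | C_t = 1) close to 0.9 (binomial 3-SE band)
  in1 <- panel$C == 1L
  phat <- mean(panel$data$Y[, , 1][in1] == 1L)
  se <- sqrt(0.9 * 0.1 / sum(in1))
  expect_lt(abs(phat - 0.9), 3 * se)
  # P(C_1 = 2 | U = 1, z near 1) close to 0.9 via a local window
  win <- abs(panel$data$Z[, 1, 1] - 1) < 0.05 & panel$U == 1L
  expect_gt(sum(win), 500)
  expect_lt(abs(mean(panel$C[win, 1] == 2L) - 0.9), 0.02)
})

test_that("misspecified generation adds a quadratic covariate effect", {
  sc_q <- lcpm_scenario("strong", N = 30000, misspecified = TRUE)
  sc_l <- lcpm_scenario("strong", N = 30000)
  pq <- generate_panel(sc_q, seed = 85)
  pl <- generate_panel(sc_l, seed = 85)
  # same covariate draws, different class-assignment law
  expect_identical(pq$data$Z, pl$data$Z)
  expect_false(identical(pq$C, pl$C))
  # at z near -1 the quadratic term (coef = half the slope) separates the
  # two generators within profile 1: logits differ by 0.5 * (log 9 - 1)
  for (panel in list(pq, pl)) {
    win <- abs(panel$data$Z[, 1, 1] + 1) < 0.25 & panel$U == 1L
    expect_gt(sum(win), 50)
  }
  wq <- abs(pq$data$Z[, 1, 1] + 1) < 0.25 & pq$U == 1L
  wl <- abs(pl$data$Z[, 1, 1] + 1) < 0.25 & pl$U == 1L
  expect_gt(mean(pq$C[wq, 1] == 2L), mean(pl$C[wl, 1] == 2L))
})

test_that("label alignment recovers swaps exactly and is idempotent", {
  set.seed(86)
  sc <- lcpm_scenario("strong")
  truth <- sc$true_params
  # identity
  al <- align_labels(truth, truth)
  expect_identical(al$perm_class, 1:2)
  expect_identical(al$perm_profile, 1:2)
  expect_equal(al$params$rho, truth$rho)
  expect_equal(al$params$beta, truth$beta)
  expect_equal(al$params$alpha, truth$alpha)
  # a deliberate class+profile swap is undone
  sw <- truth
  sw$rho <- truth$rho[, , 2:1, , drop = FALSE]
  dim(sw$rho) <- dim(truth$rho)
  sw$alpha <- truth$alpha[, 2:1, 2:1, , drop = FALSE]
  dim(sw$alpha) <- dim(truth$alpha)
  for (t in 1:3) for (u in 1:2) {
    a <- matrix(sw$alpha[t, u, , ], nrow = 2)
    sw$alpha[t, u, , ] <- sweep(a, 2, a[1, ])
  }
  b <- truth$beta[2:1, , drop = FALSE]
  sw$beta <- sweep(b, 2, b[1, ])
  al2 <- align_labels(sw, truth)
  expect_identical(al2$perm_class, c(2L, 1L))
  expect_identical(al2$perm_profile, c(2L, 1L))
  expect_equal(al2$params$rho, truth$rho, tolerance = 1e-12)
  expect_equal(al2$params$beta, truth$beta, tolerance = 1e-12)
  expect_equal(al2$params$alpha, truth$alpha, tolerance = 1e-12)
  # aligning an already-aligned estimate changes nothing
  est <- random_params(sc$spec)
  a1 <- align_labels(est, truth)$params
  a2 <- align_labels(a1, truth)$params
  expect_equal(a1$rho, a2$rho, tolerance = 1e-12)
  expect_equal(a1$beta, a2$beta, tolerance = 1e-12)
})

test_that("noiseless emissions give perfect class recovery", {
  sp <- lcpm_spec(K = 2, S = 2, T = 3, M = 4, r = 2)
  rho <- array(0, dim = c(4, 2, 2))
  rho[, 1, 1] <- 1; rho[, 2, 1] <- 0
  rho[, 1, 2] <- 0; rho[, 2, 2] <- 1
  beta <- matrix(0, 2, 1)
  alpha <- array(0, dim = c(3, 2, 2, 1))
  alpha[, 1, 2, 1] <- 1.5
  alpha[, 2, 2, 1] <- -1.5
  p <- lcpm_params(sp, rho, beta, alpha)
  set.seed(87)
  sim <- simulate_from_params(p, N = 60)
  pred <- predict_memberships(p, sim$data)
  expect_identical(pred$C_hat, sim$C)
})
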