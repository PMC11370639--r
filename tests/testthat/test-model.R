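test_that("forward pass produces valid softmax probabilities", {
  inst <- random_instance(1, p = 5, n = 4, c = 3)

  # zero classifier: every class equally likely
  p0 <- gpn_params(beta = matrix(0, 5, 3))
  fw <- gpn_forward(inst$X, inst$L, p0)
  expect_equal(unname(fw$P), matrix(1 / 3, 3, 4))

  # two-class shift invariance: scores (a, a + ln 3) -> (0.25, 0.75)
  Xs <- matrix(1, 1, 1)
  Ls <- matrix(0, 1, 1)
  beta2 <- matrix(c(2, 2 + log(3)), 1, 2)
  fw2 <- gpn_forward(Xs, Ls, gpn_params(mu = 0, beta = beta2))
  expect_equal(as.vector(fw2$P), c(0.25, 0.75), tolerance = 1e-12)

  fw3 <- gpn_forward(inst$X, inst$L, inst$params)
  expect_equal(unname(colSums(fw3$P)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(fw3$P > 0 & fw3$P < 1))
})

test_that("loss matches hand computation", {
  Y <- diag(3)
  unif <- matrix(1 / 3, 3, 3)
  p <- gpn_params(beta = matrix(0, 2, 3), delta = 1e-3)
  reg <- p$delta * (p$alpha^2 + p$mu^2)
  expect_equal(gpn_loss(unif, Y, p) - reg, log(3), tolerance = 1e-12)

  # near-perfect prediction: cross-entropy tends to zero
  eps <- 1e-9
  Pgood <- (1 - 3 * eps / 2) * diag(3) + eps / 2
  expect_lt(gpn_loss(Pgood, Y, p) - reg, 1e-8)

  # explicit scalar case
  P <- matrix(c(0.7, 0.3, 0.2, 0.8), 2)
  Y2 <- matrix(c(1, 0, 0, 1), 2)
  p2 <- gpn_params(alpha = 0.5, mu = 2, beta = matrix(c(1, -1), 1, 2),
                   delta = 0.001)
  hand <- -(log(0.7) + log(0.8)) / 2 + 0.001 * (0.5^2 + 2^2 + 1 + 1)
  expect_equal(gpn_loss(P, Y2, p2), hand, tolerance = 1e-12)

  expect_error(gpn_loss(P - 1, Y2, p2), "strictly positive")
})

test_that("gradients reduce to the ridge term in degenerate cases", {
  inst <- random_instance(2)
  d <- inst$params$delta

  # perfect predictions: only the ridge term remains for beta
  expect_equal(unname(gpn_grad_beta(inst$X, inst$Y, inst$Y, inst$params)),
               unname(2 * d * inst$params$beta))

  # mu = 0 propagation changes nothing: alpha gradient is pure ridge
  fw <- gpn_forward(inst$X, inst$L, inst$params)
  expect_equal(gpn_grad_alpha(inst$X, inst$X, fw$P, inst$Y, inst$params),
               2 * d * inst$params$alpha, tolerance = 1e-12)

  # saturated combining logit: data term vanishes
  psat <- inst$params; psat$alpha <- 60
  fw <- gpn_forward(inst$X, inst$L, psat)
  expect_equal(gpn_grad_alpha(inst$X, fw$F, fw$P, inst$Y, psat),
               2 * d * psat$alpha, tolerance = 1e-10)

  # edgeless graph: smoothness gradient is pure ridge
  L0 <- matrix(0, nrow(inst$X), nrow(inst$X))
  fw0 <- gpn_forward(inst$X, L0, inst$params)
  expect_equal(gpn_grad_mu(inst$X, L0, fw0$P, inst$Y, inst$params),
               2 * d * inst$params$mu, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  for (s in 1:10) {
    set.seed(s)
    inst <- random_instance(s, p = sample(3:8, 1), n = sample(3:8, 1))
    fw <- gpn_forward(inst$X, inst$L, inst$params)

    g_b <- gpn_grad_beta(fw$Z, fw$P, inst$Y, inst$params)
    g_b_num <- num_grad_beta(inst$X, inst$L, inst$Y, inst$params)
    expect_lt(max(abs(g_b - g_b_num)) / max(abs(g_b_num)), 1e-5)

    g_a <- gpn_grad_alpha(inst$X, fw$F, fw$P, inst$Y, inst$params)
    g_a_num <- num_grad_scalar(inst$X, inst$L, inst$Y, inst$params, "alpha")
    expect_lt(abs(g_a - g_a_num) / max(abs(g_a_num), 1e-8), 1e-5)

    g_m <- gpn_grad_mu(inst$X, inst$L, fw$P, inst$Y, inst$params)
    g_m_num <- num_grad_scalar(inst$X, inst$L, inst$Y, inst$params, "mu")
    expect_lt(abs(g_m - g_m_num) / max(abs(g_m_num), 1e-8), 1e-4)
  }
})

test_that("single-sample beta gradient matches the outer product", {
  Z <- matrix(c(1, 2), 2, 1)
  Y <- matrix(c(1, 0), 2, 1)
  P <- matrix(c(0.6, 0.4), 2, 1)
  params <- gpn_params(beta = matrix(0, 2, 2))
  expect_equal(gpn_grad_beta(Z, P, Y, params), Z %*% t(P - Y))
})

test_that("training separates a separable toy problem deterministically", {
  set.seed(10)
  net <- random_network(6, seed = 10)
  L <- graph_laplacian(net)
  n <- 30
  lab <- rep(c("a", "b", "c"), each = 10)
  means <- matrix(0, 6, 3, dimnames = list(net$proteins, c("a", "b", "c")))
  means[1:2, 1] <- 4; means[3:4, 2] <- 4; means[5:6, 3] <- 4
  X <- means[, lab] + matrix(rnorm(6 * n, sd = 0.1), 6, n)
  colnames(X) <- sprintf("s%02d", 1:n)
  Y <- one_hot_labels(lab); colnames(Y) <- colnames(X)

  m <- gpn_train(X, L, Y, mu_init = 1, epochs = 800, seed = 3)
  fw <- gpn_forward(X, L, m$params)
  acc <- mean(rownames(Y)[apply(fw$P, 2, which.max)] ==
              rownames(Y)[apply(Y, 2, which.max)])
  expect_equal(acc, 1.0)

  # loss decreases after burn-in
  lh <- m$loss_history
  burn <- lh[-(1:50)]
  expect_true(all(diff(burn) <= 1e-6))
  expect_lt(lh[length(lh)], lh[1])

  # determinism: same seed, bit-identical history
  m2 <- gpn_train(X, L, Y, mu_init = 1, epochs = 800, seed = 3)
  expect_identical(m$loss_history, m2$loss_history)

  # heavy regularization crushes beta and pushes P to uniform
  mreg <- gpn_train(X, L, Y, mu_init = 1, epochs = 400, seed = 3, delta = 1e3)
  expect_lt(max(abs(mreg$params$beta)), 1e-2)
  fwreg <- gpn_forward(X, L, mreg$params)
  expect_lt(max(abs(fwreg$P - 1 / 3)), 0.05)
})

test_that("gradient norms are small at a trained optimum", {
  set.seed(21)
  net <- random_network(5, seed = 21)
  L <- graph_laplacian(net)
  X <- matrix(rnorm(5 * 20), 5, 20, dimnames = list(net$proteins, NULL))
  colnames(X) <- sprintf("s%d", 1:20)
  lab <- rep(c("a", "b"), 10)
  Y <- one_hot_labels(lab); colnames(Y) <- colnames(X)
  m <- gpn_train(X, L, Y, mu_init = 0.5, epochs = 4000, seed = 1, tol = 0)
  fw <- gpn_forward(X, L, m$params)
  expect_lt(max(abs(gpn_grad_beta(fw$Z, fw$P, Y, m$params))), 1e-2)
  expect_lt(abs(gpn_grad_alpha(X, fw$F, fw$P, Y, m$params)), 1e-2)
  expect_lt(abs(gpn_grad_mu(X, L, fw$P, Y, m$params)), 1e-2)
  expect_true(m$theta > 0 && m$theta < 1)
  expect_true(all(m$loss_history >= 0))
})

test_that("prediction reproduces the forward pass and handles edge cases", {
  inst <- random_instance(5, p = 6, n = 10, c = 3)
  colnames(inst$X) <- sprintf("s%d", 1:10)
  colnames(inst$Y) <- colnames(inst$X)
  m <- gpn_train(inst$X, inst$L, inst$Y, mu_init = 1, epochs = 50, seed = 2)

  pred <- predict(m, inst$X, inst$L)
  fw <- gpn_forward(inst$X, inst$L, m$params)
  expect_equal(unname(pred$P), unname(fw$P), tolerance = 1e-12)

  single <- predict(m, inst$X[, 1, drop = FALSE], inst$L)
  expect_equal(sum(single$P), 1, tolerance = 1e-12)

  none <- predict(m, inst$X[, 0, drop = FALSE], inst$L)
  expect_equal(ncol(none$P), 0L)
  expect_length(none$labels, 0L)

  Xbad <- inst$X
  rownames(Xbad)[1] <- "OTHER"
  expect_error(predict(m, Xbad, inst$L), "mismatch")
})

test_that("model JSON serialization round-trips predictions", {
  inst <- random_instance(6, p = 5, n = 8, c = 3)
  colnames(inst$X) <- sprintf("s%d", 1:8)
  colnames(inst$Y) <- colnames(inst$X)
  m <- gpn_train(inst$X, inst$L, inst$Y, mu_init = c(0.1, 1), epochs = 40,
                 seed = 9, standardize = TRUE)
  tf <- tempfile(fileext = ".json")
  write_gpn(m, tf)
  m2 <- read_gpn(tf)
  expect_identical(m2$class_names, m$class_names)
  expect_equal(m2$params$beta, m$params$beta)
  p1 <- predict(m, inst$X, inst$L)
  p2 <- predict(m2, inst$X, inst$L)
  expect_equal(p1$P, p2$P, tolerance = 1e-12)
})

test_that("grid selection honors the validation split when given", {
  inst <- random_instance(7, p = 6, n = 24, c = 3)
  colnames(inst$X) <- sprintf("s%d", 1:24)
  colnames(inst$Y) <- colnames(inst$X)
  m <- gpn_train(inst$X, inst$L, inst$Y, mu_init = c(0.1, 1, 10),
                 epochs = 60, seed = 4,
                 X_val = inst$X, Y_val = inst$Y)
  expect_true("val_auroc" %in% colnames(m$mu_grid))
  expect_equal(nrow(m$mu_grid), 3L)
  expect_true(all(m$mu_grid$val_auroc >= 0 & m$mu_grid$val_auroc <= 1))
  expect_error(gpn_train(inst$X, inst$L, inst$Y, select = "val_auroc"),
               "X_val")
})
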