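# Brute-force oracles: AUROC as the fraction of correctly ordered
# positive-negative pairs (ties count 1/2); AUPRC by exhaustive
# threshold enumeration at every distinct score.
auroc_pairs <- function(s, y) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
auprc_thresholds <- function(s, y) {
  ths <- sort(unique(s), decreasing = TRUE)
  rec0 <- 0; area <- 0
  for (t in ths) {
    tp <- sum(y == 1 & s >= t); fp <- sum(y == 0 & s >= t)
    rec <- tp / sum(y == 1); prec <- tp / (tp + fp)
    area <- area + (rec - rec0) * prec
    rec0 <- rec
  }
  area
}

as_ovr <- function(scores, y) {
  P <- rbind(scores, 1 - scores)
  Y <- rbind(y, 1 - y)
  rownames(P) <- rownames(Y) <- c("pos", "neg")
  list(P = P, Y = Y)
}

test_that("AUROC matches exhaustive pair counting", {
  s <- c(0.9, 0.8, 0.7, 0.6); y <- c(1, 0, 1, 0)
  o <- as_ovr(s, y)
  r <- auroc_ovr(o$P, o$Y)
  expect_equal(unname(r$per_class["pos"]), 0.75)
  expect_equal(unname(r$per_class["pos"]), auroc_pairs(s, y))

  # perfect ranking and fully tied scores
  expect_equal(unname(auroc_ovr(as_ovr(c(3, 4, 1, 2), c(1, 1, 0, 0))$P,
                                as_ovr(c(3, 4, 1, 2), c(1, 1, 0, 0))$Y)$per_class["pos"]), 1.0)
  tied <- as_ovr(rep(0.5, 6), c(1, 0, 1, 0, 0, 1))
  expect_equal(unname(auroc_ovr(tied$P, tied$Y)$per_class["pos"]), 0.5)

  # random cases against the brute-force oracle
  for (s0 in 1:10) {
    set.seed(s0)
    sc <- round(runif(15), 2)        # rounding forces ties
    y0 <- rbinom(15, 1, 0.4)
    if (length(unique(y0)) < 2) next
    o0 <- as_ovr(sc, y0)
    expect_equal(unname(auroc_ovr(o0$P, o0$Y)$per_class["pos"]),
                 auroc_pairs(sc, y0))
  }
})

test_that("AUROC cross-checks against pROC and is transform invariant", {
  set.seed(33)
  sc <- rnorm(40); y <- rbinom(40, 1, 0.5)
  o <- as_ovr(sc, y)
  ours <- unname(auroc_ovr(o$P, o$Y)$per_class["pos"])
  ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)

  # complement symmetry and monotone-transform invariance
  oneg <- as_ovr(-sc, y)
  expect_equal(unname(auroc_ovr(oneg$P, oneg$Y)$per_class["pos"]), 1 - ours)
  omono <- as_ovr(exp(3 * sc), y)
  expect_equal(unname(auroc_ovr(omono$P, omono$Y)$per_class["pos"]), ours)
})

test_that("AUPRC matches exhaustive threshold enumeration", {
  s <- c(0.9, 0.8, 0.7, 0.6); y <- c(1, 0, 1, 0)
  o <- as_ovr(s, y)
  expect_equal(unname(auprc_ovr(o$P, o$Y)$per_class["pos"]),
               auprc_thresholds(s, y))

  perfect <- as_ovr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(unname(auprc_ovr(perfect$P, perfect$Y)$per_class["pos"]), 1.0)

  # constant score: area equals prevalence
  tied <- as_ovr(rep(0.3, 10), c(rep(1, 3), rep(0, 7)))
  expect_equal(unname(auprc_ovr(tied$P, tied$Y)$per_class["pos"]), 0.3)

  for (s0 in 1:10) {
    set.seed(100 + s0)
    sc <- round(runif(12), 1)
    y0 <- rbinom(12, 1, 0.4)
    if (length(unique(y0)) < 2) next
    o0 <- as_ovr(sc, y0)
    expect_equal(unname(auprc_ovr(o0$P, o0$Y)$per_class["pos"]),
                 auprc_thresholds(sc, y0))
  }
})

test_that("degenerate classes yield NA with a warning", {
  P <- matrix(runif(9), 3, dimnames = list(c("a", "b", "c"), NULL))
  Y <- matrix(0, 3, 3, dimnames = dimnames(P))
  Y["a", 1:2] <- 1; Y["b", 3] <- 1          # class c never occurs
  expect_warning(r <- auroc_ovr(P, Y), "c")
  expect_true(is.na(r$per_class["c"]))
  expect_false(is.na(r$macro))
})

test_that("mean probability by group averages within true classes", {
  Y <- diag(3); rownames(Y) <- c("a", "b", "c")
  expect_equal(unname(mean_probability_by_group(Y, Y)), diag(3))
  U <- matrix(1 / 3, 3, 3)
  expect_equal(unname(mean_probability_by_group(U, Y)), U)

  # three samples, hand arithmetic
  P <- matrix(c(0.5, 0.3, 0.2,
                0.6, 0.2, 0.2,
                0.1, 0.8, 0.1), 3)
  Y3 <- matrix(c(1, 0, 0, 1, 0, 0, 0, 1, 0), 3)
  rownames(P) <- rownames(Y3) <- c("a", "b", "c")
  M <- mean_probability_by_group(P, Y3)
  expect_equal(unname(M["a", ]), c(0.55, 0.25, 0.20))
  expect_equal(unname(M["b", ]), c(0.1, 0.8, 0.1))
  expect_equal(unname(rowSums(M, na.rm = TRUE))[1:2], c(1, 1))
})

test_that("metric report bundles and serializes all pieces", {
  set.seed(8)
  inst <- random_instance(8, p = 5, n = 30, c = 3)
  fw <- gpn_forward(inst$X, inst$L, inst$params)
  rep_ <- metric_report(fw$P, inst$Y)
  expect_s3_class(rep_, "gpn_metrics")
  expect_equal(sum(rep_$n_per_class), 30)
  expect_equal(unname(rowSums(rep_$mean_prob_matrix)), rep(1, 3),
               tolerance = 1e-9)
  tf <- tempfile(fileext = ".json")
  write_metric_report(rep_, tf)
  back <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_equal(back$auroc$macro, rep_$auroc_macro)
})

test_that("sweep surface is structurally constant where propagation is inert", {
  set.seed(12)
  net <- random_network(6, seed = 12)
  L <- graph_laplacian(net)
  n <- 24
  lab <- rep(c("a", "b", "c"), 8)
  X <- matrix(rnorm(6 * n), 6, n, dimnames = list(net$proteins, sprintf("s%d", 1:n)))
  X[1, lab == "a"] <- X[1, lab == "a"] + 2
  X[4, lab == "b"] <- X[4, lab == "b"] + 2
  Y <- one_hot_labels(lab); colnames(Y) <- colnames(X)
  sw <- parameter_sweep(X, L, Y, X, Y, mu_grid = c(0, 0.1, 10),
                        theta_grid = c(0, 0.5, 1))
  # theta = 0: F never enters, all mu identical
  th0 <- sw$auroc_macro[sw$theta == 0]
  expect_equal(max(th0) - min(th0), 0)
  # mu = 0: F equals X, all theta identical
  mu0 <- sw$auroc_macro[sw$mu == 0]
  expect_equal(max(mu0) - min(mu0), 0)
  expect_equal(nrow(sw), 9L)
  expect_length(attr(sw, "mu_means"), 3L)
})
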