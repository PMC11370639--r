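# Shared fixtures: small graphs, random instances, and a full-loss
# evaluator used as the finite-difference oracle.

path_network <- function(n = 3, weight = 1) {
  proteins <- LETTERS[seq_len(n)]
  edges <- data.frame(protein1 = proteins[-n], protein2 = proteins[-1],
                      weight = weight, stringsAsFactors = FALSE)
  ppi_network(edges, proteins)
}

# Erdos-Renyi-style weighted network; connected = add a spanning path.
random_network <- function(p, seed, density = 0.4, connected = TRUE) {
  set.seed(seed)
  proteins <- sprintf("N%02d", seq_len(p))
  W <- matrix(0, p, p, dimnames = list(proteins, proteins))
  idx <- which(upper.tri(W), arr.ind = TRUE)
  on <- runif(nrow(idx)) < density
  W[idx[on, , drop = FALSE]] <- runif(sum(on), 0.1, 1)
  if (connected) {
    for (i in seq_len(p - 1)) if (W[i, i + 1] == 0) W[i, i + 1] <- runif(1, 0.1, 1)
  }
  W[lower.tri(W)] <- 0
  W <- W + t(W)
  structure(list(proteins = proteins, W = W), class = "ppi_network")
}

# Random classification instance for gradient checks.
random_instance <- function(seed, p = 6, n = 5, c = 3) {
  set.seed(seed)
  net <- random_network(p, seed + 1000, density = 0.5)
  L <- graph_laplacian(net)
  X <- matrix(rnorm(p * n), p, n,
              dimnames = list(net$proteins, sprintf("S%02d", seq_len(n))))
  lab <- sample(letters[seq_len(c)], n, replace = TRUE)
  # guarantee every class appears at least once when n >= c
  if (n >= c) lab[seq_len(c)] <- letters[seq_len(c)]
  Y <- one_hot_labels(lab, letters[seq_len(c)])
  colnames(Y) <- colnames(X)
  params <- gpn_params(alpha = rnorm(1, sd = 0.5),
                       mu = runif(1, 0.2, 2),
                       beta = matrix(rnorm(p * c, sd = 0.5), p, c),
                       delta = 1e-3)
  list(X = X, L = L, Y = Y, params = params, net = net)
}

# Total objective (cross-entropy + ridge) as a function of raw
# parameters; recomputes the whole forward pass, so central differences
# of this function are an independent oracle for the analytic gradients.
full_loss <- function(X, L, Y, alpha, mu, beta, delta) {
  params <- gpn_params(alpha = alpha, mu = mu, beta = beta, delta = delta)
  fw <- gpn_forward(X, L, params)
  gpn_loss(pmax(fw$P, 1e-300), Y, params)
}

num_grad_beta <- function(X, L, Y, params, h = 1e-5) {
  b <- params$beta
  g <- b * 0
  for (i in seq_len(nrow(b))) for (j in seq_len(ncol(b))) {
    bp <- b; bp[i, j] <- b[i, j] + h
    bm <- b; bm[i, j] <- b[i, j] - h
    g[i, j] <- (full_loss(X, L, Y, params$alpha, params$mu, bp, params$delta) -
                full_loss(X, L, Y, params$alpha, params$mu, bm, params$delta)) / (2 * h)
  }
  g
}

num_grad_scalar <- function(X, L, Y, params, which, h = 1e-5) {
  pv <- params[[which]]
  up <- params; up[[which]] <- pv + h
  dn <- params; dn[[which]] <- pv - h
  (full_loss(X, L, Y, up$alpha, up$mu, up$beta, up$delta) -
   full_loss(X, L, Y, dn$alpha, dn$mu, dn$beta, dn$delta)) / (2 * h)
}

# Quadratic objective of the propagation problem.
propagation_objective <- function(Fmat, X, L, mu) {
  sum((Fmat - X)^2) + mu * sum(diag(t(Fmat) %*% L %*% Fmat))
}
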