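#' Parameter set of a graph propagational network
#'
#' Bundles the trainable parameters: combining logit `alpha` (mapped to
#' the combining ratio theta by the logistic function), smoothness `mu`,
#' and the p x c classifier matrix `beta`, plus the fixed ridge weight
#' `delta` applied to `||alpha||^2 + ||mu||^2 + ||beta||^2`.
#'
#' @param alpha Combining logit, scalar. Default 0 (theta = 0.5).
#' @param mu Smoothness, scalar >= 0.
#' @param beta Numeric p x c matrix of classifier coefficients.
#' @param delta Regularization weight, scalar > 0. Default 1e-3.
#' @return A `gpn_params` list.
#' @export
gpn_params <- function(alpha = 0, mu = 1, beta, delta = 1e-3) {
  beta <- as.matrix(beta)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) {
    stop("delta must be a positive scalar")
  }
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0) {
    stop("mu must be a scalar >= 0")
  }
  if (!all(is.finite(beta))) stop("beta must be finite")
  structure(list(alpha = alpha, mu = mu, beta = beta, delta = delta),
            class = "gpn_params")
}

#' Forward pass of the GPN
#'
#' Propagates `X` to the interactive effect `F = (I + mu L)^{-1} X`,
#' combines it with `X` as `Z = theta F + (1 - theta) X`, and scores
#' classes by a column-wise softmax of `beta' Z` (computed with
#' per-column max subtraction for numerical stability).
#'
#' @param X Expression matrix, proteins x samples.
#' @param L Graph Laplacian aligned to the rows of `X`.
#' @param params A `gpn_params`.
#' @return List with `F`, `theta`, `Z`, and class-probability matrix `P`
#'   (c x n, columns summing to 1).
#' @export
gpn_forward <- function(X, L, params) {
  stopifnot(inherits(params, "gpn_params"))
  X <- as.matrix(X)
  Fmat <- propagate(X, L, params$mu)
  if (!all(is.finite(Fmat))) stop("non-finite values in propagation stage")
  cmb <- combine_effects(X, Fmat, params$alpha)
  scores <- crossprod(params$beta, cmb$Z)       # c x n
  if (!all(is.finite(scores))) stop("non-finite values in classifier scores")
  P <- softmax_columns(scores)
  rownames(P) <- colnames(params$beta)
  colnames(P) <- colnames(X)
  list(F = Fmat, theta = cmb$theta, Z = cmb$Z, P = P)
}

softmax_columns <- function(S) {
  if (ncol(S) == 0L) return(S)
  S <- sweep(S, 2L, apply(S, 2L, max), "-")
  E <- exp(S)
  sweep(E, 2L, colSums(E), "/")
}

#' Regularized cross-entropy loss
#'
#' Mean cross-entropy `-(1/n) tr(Y' log P)` (natural log, probabilities
#' floored at 1e-12) plus `delta * (alpha^2 + mu^2 + ||beta||_F^2)`.
#'
#' @param P Class probabilities, c x n.
#' @param Y One-hot label matrix, c x n.
#' @param params A `gpn_params`.
#' @return Scalar loss.
#' @export
gpn_loss <- function(P, Y, params) {
  stopifnot(inherits(params, "gpn_params"))
  P <- as.matrix(P); Y <- as.matrix(Y)
  if (!all(dim(P) == dim(Y))) stop("P and Y shapes differ")
  if (any(P <= 0)) stop("P must be strictly positive")
  n <- ncol(P)
  ce <- -sum(Y * log(pmax(P, 1e-12))) / n
  reg <- params$alpha^2 + params$mu^2 + sum(params$beta^2)
  ce + params$delta * reg
}

#' Analytic gradient with respect to the classifier matrix
#'
#' `grad beta = (1/n) Z (P - Y)' + 2 delta beta`.
#'
#' @param Z Combined effect, p x n.
#' @param P Class probabilities, c x n.
#' @param Y One-hot labels, c x n.
#' @param params A `gpn_params`.
#' @return p x c matrix.
#' @export
gpn_grad_beta <- function(Z, P, Y, params) {
  stopifnot(inherits(params, "gpn_params"))
  Z <- as.matrix(Z); P <- as.matrix(P); Y <- as.matrix(Y)
  if (!all(dim(P) == dim(Y))) stop("P and Y shapes differ")
  if (ncol(Z) != ncol(P)) stop("Z and P sample counts differ")
  n <- ncol(Z)
  Z %*% t(P - Y) / n + 2 * params$delta * params$beta
}

#' Analytic gradient with respect to the combining logit
#'
#' Uses the chain rule through theta: `dZ/dalpha = theta (1-theta) (F - X)`,
#' giving
#' `grad alpha = (1/n) theta (1-theta) tr((F - X)' beta (P - Y)) + 2 delta alpha`.
#'
#' @param X,F Independent and interactive effects, p x n.
#' @inheritParams gpn_grad_beta
#' @return Scalar.
#' @export
gpn_grad_alpha <- function(X, F, P, Y, params) {
  stopifnot(inherits(params, "gpn_params"))
  n <- ncol(as.matrix(X))
  theta <- stats::plogis(params$alpha)
  G <- params$beta %*% (as.matrix(P) - as.matrix(Y))   # p x n = dLoss/dZ * n
  theta * (1 - theta) * sum((F - X) * G) / n + 2 * params$delta * params$alpha
}

#' Analytic gradient with respect to the smoothness
#'
#' From the derivative of the inverse propagation operator,
#' `d Phi^{-1} / d mu = -Phi^{-1} L Phi^{-1}` with `Phi = I + mu L`:
#' `grad mu = -(theta/n) tr((Phi^{-1} L Phi^{-1} X)' beta (P - Y)) + 2 delta mu`.
#' Implemented with two positive-definite solves; no inverse is formed.
#'
#' @param X Expression matrix, p x n.
#' @param L Graph Laplacian.
#' @inheritParams gpn_grad_beta
#' @param chol_phi Optional precomputed Cholesky factor of `I + mu L`
#'   (reused during training).
#' @return Scalar.
#' @export
gpn_grad_mu <- function(X, L, P, Y, params, chol_phi = NULL) {
  stopifnot(inherits(params, "gpn_params"))
  X <- as.matrix(X)
  n <- ncol(X)
  theta <- stats::plogis(params$alpha)
  R <- if (is.null(chol_phi)) phi_chol(L, params$mu) else chol_phi
  Fmat <- phi_solve_chol(R, X)
  H <- phi_solve_chol(R, L %*% Fmat)                  # Phi^{-1} L Phi^{-1} X
  G <- params$beta %*% (as.matrix(P) - as.matrix(Y))
  -(theta / n) * sum(H * G) + 2 * params$delta * params$mu
}

#' Train a graph propagational network
#'
#' Full-batch ADAM on `(alpha, mu, beta)` using the analytic gradients.
#' The smoothness is projected back to `mu >= 0` after each step so the
#' propagation operator stays positive definite. When `mu_init` has
#' several values, one model is trained per value (each grid member uses
#' the same seeded `beta` initialization) and one member is selected:
#' by held-out macro AUROC when a validation split is supplied, by best
#' training loss otherwise. Training-loss selection systematically
#' favors `mu = 0` -- propagated features are a linear reparametrization
#' of the raw ones, so smoothing can never lower the training objective
#' -- hence a validation split is recommended whenever the grid has more
#' than one value.
#'
#' @param X Expression matrix, proteins x samples (discovery cohort).
#' @param L Graph Laplacian aligned to `X`.
#' @param Y One-hot label matrix, classes x samples, with class rownames.
#' @param mu_init Initial smoothness value(s); default the grid
#'   `10^(-2:2)`.
#' @param alpha_init Initial combining logit, default 0 (theta = 0.5).
#' @param delta Regularization weight, default 1e-3.
#' @param lr ADAM learning rate, default 0.001.
#' @param epochs Maximum epochs per grid value, default 2000.
#' @param tol Early-stopping tolerance on the absolute change of the
#'   loss between epochs, default 1e-7.
#' @param seed Integer seed; the Gaussian `beta` initialization (sd
#'   0.01) is the only source of randomness, so runs are reproducible.
#' @param beta_sd Standard deviation of the `beta` initialization.
#' @param standardize If TRUE, per-protein z-scoring (mean/sd from the
#'   training data) is applied before propagation and stored in the
#'   model for reuse at prediction time. Default FALSE.
#' @param trainable Character subset of `c("alpha", "mu", "beta")`;
#'   parameters not listed are frozen at their initial value (used for
#'   ablations and the parameter sweep).
#' @param X_val,Y_val Optional validation split used only to pick the
#'   `mu_init` grid member.
#' @param select Grid-selection rule: `"auto"` (default) uses
#'   `"val_auroc"` when `X_val`/`Y_val` are given and `"train_loss"`
#'   otherwise.
#' @return A `gpn` model: `params`, `theta`, `loss_history`, `epochs_run`,
#'   `mu_grid` (per-value final losses and, when computed, validation
#'   AUROCs), `class_names`, `proteins`, standardization centers/scales
#'   if requested.
#' @export
gpn_train <- function(X, L, Y,
                      mu_init = 10^(-2:2), alpha_init = 0, delta = 1e-3,
                      lr = 0.001, epochs = 2000, tol = 1e-7, seed = 1,
                      beta_sd = 0.01, standardize = FALSE,
                      trainable = c("alpha", "mu", "beta"),
                      X_val = NULL, Y_val = NULL,
                      select = c("auto", "val_auroc", "train_loss")) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("X and Y sample counts differ")
  if (any(colSums(Y) != 1)) stop("Y must be one-hot: every column sums to 1")
  if (lr <= 0) stop("lr must be > 0")
  if (any(mu_init < 0)) stop("mu_init must be >= 0")
  trainable <- match.arg(trainable, several.ok = TRUE)
  select <- match.arg(select)
  if (select == "auto") {
    select <- if (is.null(X_val)) "train_loss" else "val_auroc"
  }
  if (select == "val_auroc" && (is.null(X_val) || is.null(Y_val))) {
    stop("select = \"val_auroc\" needs X_val and Y_val")
  }
  if (is.null(rownames(Y))) rownames(Y) <- paste0("class", seq_len(nrow(Y)))

  center <- scale_ <- NULL
  if (standardize) {
    center <- rowMeans(X)
    scale_ <- apply(X, 1L, stats::sd)
    scale_[scale_ == 0] <- 1
    X <- (X - center) / scale_
  }

  p <- nrow(X); c <- nrow(Y)
  set.seed(as.integer(seed))
  beta0 <- matrix(stats::rnorm(p * c, sd = beta_sd), p, c,
                  dimnames = list(rownames(X), rownames(Y)))

  fits <- lapply(mu_init, function(mu0) {
    gpn_fit_one(X, L, Y, alpha_init, mu0, beta0, delta, lr, epochs, tol,
                trainable)
  })
  final_losses <- vapply(fits, function(f) f$best_loss, numeric(1))
  grid <- data.frame(mu_init = mu_init, final_loss = final_losses)
  if (select == "val_auroc") {
    X_val <- as.matrix(X_val)
    if (standardize) X_val <- (X_val - center) / scale_
    val_auroc <- vapply(fits, function(f) {
      fw <- gpn_forward(X_val, L, f$params)
      auroc_ovr(fw$P, Y_val)$macro
    }, numeric(1))
    grid$val_auroc <- val_auroc
    best <- which.max(val_auroc)
  } else {
    best <- which.min(final_losses)
  }
  fit <- fits[[best]]

  structure(list(
    params = fit$params,
    theta = stats::plogis(fit$params$alpha),
    loss_history = fit$loss_history,
    epochs_run = fit$epochs_run,
    mu_grid = grid,
    class_names = rownames(Y),
    proteins = rownames(X),
    standardize = standardize, center = center, scale = scale_,
    seed = as.integer(seed)
  ), class = "gpn")
}

# Single ADAM run at one initial mu. Cholesky factor of I + mu*L is
# recomputed only when mu changes (it is frozen in ablation/sweep runs).
gpn_fit_one <- function(X, L, Y, alpha, mu, beta, delta, lr, epochs, tol,
                        trainable) {
  n <- ncol(X)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  m_a <- v_a <- m_m <- v_m <- 0
  m_b <- v_b <- matrix(0, nrow(beta), ncol(beta))
  loss_history <- numeric(0)
  best_loss <- Inf
  best <- list(alpha = alpha, mu = mu, beta = beta)
  R <- phi_chol(L, mu); mu_of_R <- mu
  prev_loss <- Inf

  for (t in seq_len(epochs)) {
    if (mu != mu_of_R) { R <- phi_chol(L, mu); mu_of_R <- mu }
    Fmat <- phi_solve_chol(R, X)
    theta <- stats::plogis(alpha)
    Z <- theta * Fmat + (1 - theta) * X
    P <- softmax_columns(crossprod(beta, Z))
    params <- gpn_params(alpha = alpha, mu = mu, beta = beta, delta = delta)
    loss <- gpn_loss(pmax(P, 1e-12), Y, params)
    if (!is.finite(loss)) {
      stop("training diverged: non-finite loss at epoch ", t,
           "; last finite loss ",
           if (length(loss_history)) format(loss_history[length(loss_history)])
           else "none")
    }
    loss_history <- c(loss_history, loss)
    if (loss < best_loss) {
      best_loss <- loss
      best <- list(alpha = alpha, mu = mu, beta = beta)
    }

    Resid <- P - Y
    G <- beta %*% Resid                      # shared term for alpha/mu grads
    if ("beta" %in% trainable) {
      g_b <- Z %*% t(Resid) / n + 2 * delta * beta
      m_b <- b1 * m_b + (1 - b1) * g_b
      v_b <- b2 * v_b + (1 - b2) * g_b^2
      beta <- beta - lr * (m_b / (1 - b1^t)) / (sqrt(v_b / (1 - b2^t)) + eps)
    }
    if ("alpha" %in% trainable) {
      g_a <- theta * (1 - theta) * sum((Fmat - X) * G) / n + 2 * delta * alpha
      m_a <- b1 * m_a + (1 - b1) * g_a
      v_a <- b2 * v_a + (1 - b2) * g_a^2
      alpha <- alpha - lr * (m_a / (1 - b1^t)) / (sqrt(v_a / (1 - b2^t)) + eps)
    }
    if ("mu" %in% trainable) {
      H <- phi_solve_chol(R, L %*% Fmat)
      g_m <- -(theta / n) * sum(H * G) + 2 * delta * mu
      m_m <- b1 * m_m + (1 - b1) * g_m
      v_m <- b2 * v_m + (1 - b2) * g_m^2
      mu <- mu - lr * (m_m / (1 - b1^t)) / (sqrt(v_m / (1 - b2^t)) + eps)
      mu <- max(mu, 0)
    }
    if (abs(prev_loss - loss) < tol) break
    prev_loss <- loss
  }
  list(params = gpn_params(alpha = best$alpha, mu = best$mu,
                           beta = best$beta, delta = delta),
       loss_history = loss_history, best_loss = best_loss,
       epochs_run = length(loss_history))
}

#' @export
print.gpn <- function(x, ...) {
  cat("graph propagational network\n")
  cat(sprintf("  proteins: %d, classes: %s\n", length(x$proteins),
              paste(x$class_names, collapse = "/")))
  cat(sprintf("  theta = %.4f (alpha = %.4f), mu = %.4g, delta = %.3g\n",
              x$theta, x$params$alpha, x$params$mu, x$params$delta))
  cat(sprintf("  final training loss %.6f after %d epochs\n",
              x$loss_history[length(x$loss_history)], x$epochs_run))
  invisible(x)
}

#' Predict class probabilities for new samples
#'
#' Applies the trained forward pass to held-out samples: the new
#' expression matrix is propagated with the same Laplacian and the
#' trained smoothness, combined with the trained theta and scored by the
#' trained classifier.
#'
#' @param object A fitted `gpn` model.
#' @param X_new Expression matrix, proteins x samples, rows in the
#'   model's protein order.
#' @param L Graph Laplacian (same network used in training).
#' @param ... Unused.
#' @return List with `P` (c x n probabilities) and `labels` (argmax
#'   class per sample).
#' @export
predict.gpn <- function(object, X_new, L, ...) {
  X_new <- as.matrix(X_new)
  if (nrow(X_new) != length(object$proteins)) {
    stop("X_new has ", nrow(X_new), " proteins; model expects ",
         length(object$proteins))
  }
  if (!is.null(rownames(X_new)) &&
      !identical(rownames(X_new), object$proteins)) {
    missing <- setdiff(object$proteins, rownames(X_new))
    extra <- setdiff(rownames(X_new), object$proteins)
    stop("protein order mismatch; missing: ",
         paste(missing, collapse = ", "), "; extra: ",
         paste(extra, collapse = ", "))
  }
  if (ncol(X_new) == 0L) {
    P <- matrix(numeric(0), nrow = length(object$class_names), ncol = 0,
                dimnames = list(object$class_names, NULL))
    return(list(P = P, labels = character(0)))
  }
  if (isTRUE(object$standardize)) {
    X_new <- (X_new - object$center) / object$scale
  }
  fw <- gpn_forward(X_new, L, object$params)
  P <- fw$P
  rownames(P) <- object$class_names
  labels <- object$class_names[apply(P, 2L, which.max)]
  names(labels) <- colnames(X_new)
  list(P = P, labels = labels)
}

#' Write a fitted GPN model to JSON
#'
#' Stores class names, protein order, all parameters (beta row-major)
#' and the standardization state at full double precision, so that
#' [read_gpn()] reproduces predictions exactly.
#'
#' @param model A `gpn` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_gpn <- function(model, path) {
  stopifnot(inherits(model, "gpn"))
  obj <- list(
    class_names = model$class_names,
    protein_order = model$proteins,
    alpha = model$params$alpha,
    mu = model$params$mu,
    beta = as.vector(t(model$params$beta)),   # row-major
    delta = model$params$delta,
    standardize = isTRUE(model$standardize),
    center = if (isTRUE(model$standardize)) unname(model$center),
    scale = if (isTRUE(model$standardize)) unname(model$scale)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a GPN model written by [write_gpn()]
#'
#' @param path JSON path.
#' @return A `gpn` object usable with [predict.gpn()].
#' @export
read_gpn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(obj$protein_order); c <- length(obj$class_names)
  beta <- matrix(obj$beta, p, c, byrow = TRUE,
                 dimnames = list(obj$protein_order, obj$class_names))
  model <- list(
    params = gpn_params(alpha = obj$alpha, mu = obj$mu, beta = beta,
                        delta = obj$delta),
    theta = stats::plogis(obj$alpha),
    loss_history = numeric(0), epochs_run = NA_integer_,
    mu_grid = NULL,
    class_names = obj$class_names, proteins = obj$protein_order,
    standardize = isTRUE(obj$standardize),
    center = if (isTRUE(obj$standardize))
      stats::setNames(obj$center, obj$protein_order),
    scale = if (isTRUE(obj$standardize))
      stats::setNames(obj$scale, obj$protein_order),
    seed = NA_integer_
  )
  structure(model, class = "gpn")
}
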