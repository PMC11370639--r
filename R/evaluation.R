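#' One-vs-rest AUROC
#'
#' Per-class area under the ROC curve computed as the Mann-Whitney rank
#' statistic with midrank tie handling (so AUROC is exactly the
#' probability that a random positive outranks a random negative, ties
#' counting 1/2), plus the unweighted macro average. A class without
#' both positives and negatives gets `NA` and is excluded from the macro
#' mean with a warning.
#'
#' @param P Score matrix, classes x samples (rows used as one-vs-rest
#'   scores; any monotone score works, probabilities included).
#' @param Y One-hot label matrix, classes x samples.
#' @return List with `per_class` (named numeric) and `macro` (scalar).
#' @export
auroc_ovr <- function(P, Y) {
  ovr_metric(P, Y, auroc_binary)
}

#' One-vs-rest AUPRC
#'
#' Per-class area under the precision-recall curve using the step-wise
#' (non-interpolated) sum of precision at each recall increment, with
#' tied scores handled as a single threshold, plus the macro average.
#' With a constant score this reduces to the class prevalence.
#'
#' @inheritParams auroc_ovr
#' @return List with `per_class` and `macro`.
#' @export
auprc_ovr <- function(P, Y) {
  ovr_metric(P, Y, auprc_binary)
}

ovr_metric <- function(P, Y, fun) {
  P <- as.matrix(P); Y <- as.matrix(Y)
  if (!all(dim(P) == dim(Y))) stop("P and Y shapes differ")
  classes <- rownames(Y)
  if (is.null(classes)) classes <- paste0("class", seq_len(nrow(Y)))
  vals <- vapply(seq_len(nrow(Y)), function(k) {
    y <- Y[k, ]
    if (all(y == 1) || all(y == 0)) return(NA_real_)
    fun(P[k, ], y)
  }, numeric(1))
  names(vals) <- classes
  if (anyNA(vals)) {
    warning("class(es) without both positives and negatives: ",
            paste(classes[is.na(vals)], collapse = ", "),
            "; macro average taken over the remaining classes")
  }
  list(per_class = vals, macro = mean(vals, na.rm = TRUE))
}

auroc_binary <- function(scores, y) {
  r <- rank(scores)                       # midranks
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

auprc_binary <- function(scores, y) {
  # walk unique thresholds from high to low; tied scores enter together
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  n1 <- sum(y)
  recall <- tp / n1
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Mean predicted probability by true diagnostic group
#'
#' Returns the c x c matrix whose (i, j) entry is the mean predicted
#' probability of class j among samples whose true class is i; the
#' diagonal is the average confidence assigned to the correct diagnosis.
#' Rows sum to 1 when `P` columns do.
#'
#' @inheritParams auroc_ovr
#' @return c x c numeric matrix (true class in rows).
#' @export
mean_probability_by_group <- function(P, Y) {
  P <- as.matrix(P); Y <- as.matrix(Y)
  if (!all(dim(P) == dim(Y))) stop("P and Y shapes differ")
  classes <- rownames(Y)
  if (is.null(classes)) classes <- paste0("class", seq_len(nrow(Y)))
  M <- t(apply(Y, 1L, function(mask) {
    if (sum(mask) == 0) return(rep(NA_real_, nrow(P)))
    rowMeans(P[, mask == 1, drop = FALSE])
  }))
  dimnames(M) <- list(true = classes, predicted = classes)
  M
}

#' Full metric report
#'
#' AUROC and AUPRC (per class and macro), class counts and the
#' mean-probability-by-group matrix, bundled for serialization.
#'
#' @inheritParams auroc_ovr
#' @return A `gpn_metrics` list.
#' @export
metric_report <- function(P, Y) {
  Y <- as.matrix(Y)
  roc <- auroc_ovr(P, Y)
  prc <- auprc_ovr(P, Y)
  structure(list(
    auroc_per_class = roc$per_class, auroc_macro = roc$macro,
    auprc_per_class = prc$per_class, auprc_macro = prc$macro,
    n_per_class = rowSums(Y),
    mean_prob_matrix = mean_probability_by_group(P, Y)
  ), class = "gpn_metrics")
}

#' @export
print.gpn_metrics <- function(x, ...) {
  cat(sprintf("macro AUROC %.4f, macro AUPRC %.4f\n",
              x$auroc_macro, x$auprc_macro))
  for (k in names(x$auroc_per_class)) {
    cat(sprintf("  %s (n=%d): AUROC %.4f, AUPRC %.4f\n", k,
                x$n_per_class[[k]], x$auroc_per_class[[k]],
                x$auprc_per_class[[k]]))
  }
  invisible(x)
}

#' Write a metric report to JSON
#'
#' @param metrics A `gpn_metrics` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(metrics, path) {
  stopifnot(inherits(metrics, "gpn_metrics"))
  obj <- list(
    auroc = list(per_class = as.list(metrics$auroc_per_class),
                 macro = metrics$auroc_macro),
    auprc = list(per_class = as.list(metrics$auprc_per_class),
                 macro = metrics$auprc_macro),
    n_per_class = as.list(metrics$n_per_class),
    mean_prob_by_group = apply(metrics$mean_prob_matrix, 1L, as.list,
                               simplify = FALSE)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Smoothness-by-combining-ratio parameter sweep
#'
#' Freezes `(mu, theta)` at each grid cell (alpha at `logit(theta)`,
#' with theta 0 and 1 treated as exact endpoints rather than infinite
#' logits), trains only the classifier `beta` on the discovery samples
#' and scores the evaluation samples, mapping how performance depends on
#' the propagation strength and the weight on the interactive effect.
#'
#' @param X,Y Discovery expression (p x n) and one-hot labels (c x n).
#' @param L Graph Laplacian aligned to `X`.
#' @param X_eval,Y_eval Evaluation split scored at each cell.
#' @param mu_grid Smoothness values; default `10^(-5:5)`.
#' @param theta_grid Combining ratios in \[0, 1\]; default
#'   `seq(0, 1, 0.1)`.
#' @param delta Ridge weight for the per-cell classifier fits.
#' @param maxit,tol Newton iteration cap and gradient tolerance for the
#'   per-cell fits; each cell's beta-only subproblem is convex and is
#'   solved to convergence so that cells differ by their features, not
#'   by how far their training got.
#' @return Long-format data frame with columns `mu`, `theta`,
#'   `auroc_macro`, `auprc_macro`; per-level averages are attached as
#'   attributes `mu_means` and `theta_means`.
#' @export
parameter_sweep <- function(X, L, Y, X_eval, Y_eval,
                            mu_grid = 10^(-5:5),
                            theta_grid = seq(0, 1, by = 0.1),
                            delta = 1e-3, maxit = 50, tol = 1e-8) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  X_eval <- as.matrix(X_eval); Y_eval <- as.matrix(Y_eval)
  if (any(theta_grid < 0 | theta_grid > 1)) stop("theta_grid must be in [0, 1]")
  rows <- vector("list", length(mu_grid) * length(theta_grid))
  k <- 0L
  for (mu in mu_grid) {
    Ftr <- propagate(X, L, mu)
    Fev <- propagate(X_eval, L, mu)
    for (theta in theta_grid) {
      Z <- theta * Ftr + (1 - theta) * X
      Zev <- theta * Fev + (1 - theta) * X_eval
      beta <- fit_softmax_newton(Z, Y, delta, maxit, tol)
      Pev <- softmax_columns(crossprod(beta, Zev))
      rownames(Pev) <- rownames(Y_eval)
      k <- k + 1L
      rows[[k]] <- data.frame(
        mu = mu, theta = theta,
        auroc_macro = auroc_ovr(Pev, Y_eval)$macro,
        auprc_macro = auprc_ovr(Pev, Y_eval)$macro
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "mu_means") <- tapply(out$auroc_macro, out$mu, mean)
  attr(out, "theta_means") <- tapply(out$auroc_macro, out$theta, mean)
  out
}

# Newton solver for the convex ridge-softmax subproblem in beta (used
# by the sweep). Deterministic: starts from beta = 0, exact Hessian
# assembled from the c x c per-sample probability structure.
fit_softmax_newton <- function(Z, Y, delta, maxit = 50, tol = 1e-8) {
  p <- nrow(Z); cc <- nrow(Y); n <- ncol(Z)
  beta <- matrix(0, p, cc)
  for (it in seq_len(maxit)) {
    P <- softmax_columns(crossprod(beta, Z))
    g <- Z %*% t(P - Y) / n + 2 * delta * beta
    if (max(abs(g)) < tol) break
    H <- matrix(0, p * cc, p * cc)
    for (k in seq_len(cc)) for (l in k:cc) {
      w <- P[k, ] * ((k == l) - P[l, ])
      B <- (Z * rep(w, each = p)) %*% t(Z) / n
      if (k == l) B <- B + 2 * delta * diag(p)
      rk <- ((k - 1) * p + 1):(k * p); rl <- ((l - 1) * p + 1):(l * p)
      H[rk, rl] <- B
      if (l > k) H[rl, rk] <- B
    }
    step <- tryCatch(
      solve(H + 1e-10 * diag(p * cc), as.vector(g)),
      error = function(e) as.vector(g))   # fall back to gradient step
    beta <- beta - matrix(step, p, cc)
  }
  beta
}

#' Write a parameter-sweep surface as long-format TSV
#'
#' @param sweep Data frame from [parameter_sweep()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.table(sweep, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
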