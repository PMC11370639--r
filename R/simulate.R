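#' Simulate a weighted PPI network with two regulation groups
#'
#' Draws a two-block stochastic network emulating a biomarker
#' subnetwork: nodes are split into an "up" and a "down" regulation
#' group, intra-group pairs connect with (slightly) higher probability
#' and carry heavier weights than inter-group pairs, and one node is
#' boosted into a hub. Edge weights are Beta-distributed on \[0, 1\]
#' with separate intra/inter means, mimicking rescaled STRING combined
#' scores.
#'
#' Defaults reproduce the shape of a 26-protein dementia biomarker
#' subnetwork: 9 upregulated and 17 downregulated proteins, expected
#' density about 0.24, intra/inter mean edge weights 0.33 and 0.25.
#'
#' @param p Number of proteins. Default 26.
#' @param n_up Number of nodes in the "up" group. Default `round(9/26*p)`.
#' @param p_intra,p_inter Connection probability within / between
#'   groups. Defaults 0.25 and 0.235 (about 43 intra and 36 inter edges
#'   at the default sizes).
#' @param w_intra_mean,w_inter_mean Mean edge weight within / between
#'   groups. Defaults 0.33 and 0.25.
#' @param w_concentration Beta concentration (shape1 + shape2) of the
#'   weight distribution. Default 20.
#' @param hub_boost If TRUE (default), the highest-degree node gains
#'   extra random edges until its degree is at least twice the median.
#' @param seed Integer seed; the same seed yields an identical network.
#' @return List with `network` (a [ppi_network()]), `groups` (named
#'   vector, `"up"`/`"down"`), and `edges` (data frame).
#' @export
simulate_ppi_network <- function(p = 26, n_up = round(9 / 26 * p),
                                 p_intra = 0.25, p_inter = 0.235,
                                 w_intra_mean = 0.33, w_inter_mean = 0.25,
                                 w_concentration = 20, hub_boost = TRUE,
                                 seed = 1) {
  if (p < 2) stop("need p >= 2")
  if (n_up < 1 || n_up >= p) stop("n_up must be in 1..(p-1)")
  set.seed(as.integer(seed))
  proteins <- sprintf("PROT%02d", seq_len(p))
  groups <- stats::setNames(rep(c("up", "down"), c(n_up, p - n_up)), proteins)

  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  same <- groups[pairs[, 1]] == groups[pairs[, 2]]
  prob <- ifelse(same, p_intra, p_inter)
  present <- stats::runif(nrow(pairs)) < prob

  draw_w <- function(is_intra, k) {
    m <- ifelse(is_intra, w_intra_mean, w_inter_mean)
    stats::rbeta(k, m * w_concentration, (1 - m) * w_concentration)
  }
  W <- matrix(0, p, p, dimnames = list(proteins, proteins))
  if (any(present)) {
    w <- draw_w(same[present], sum(present))
    W[pairs[present, , drop = FALSE]] <- w
    W[pairs[present, c(2, 1), drop = FALSE]] <- w
  }

  if (hub_boost) {
    deg <- rowSums(W > 0)
    hub <- which.max(deg)
    target <- 2 * stats::median(deg)
    candidates <- setdiff(which(W[hub, ] == 0), hub)
    while (sum(W[hub, ] > 0) < target && length(candidates) > 0) {
      j <- candidates[sample.int(length(candidates), 1L)]
      w <- draw_w(groups[hub] == groups[j], 1L)
      W[hub, j] <- W[j, hub] <- w
      candidates <- setdiff(candidates, j)
    }
  }

  net <- structure(list(proteins = proteins, W = W), class = "ppi_network")
  idx <- which(W > 0 & upper.tri(W), arr.ind = TRUE)
  edges <- data.frame(protein1 = proteins[idx[, 1]],
                      protein2 = proteins[idx[, 2]],
                      weight = W[idx], stringsAsFactors = FALSE)
  list(network = net, groups = groups, edges = edges)
}

# Largest-remainder apportionment: counts sum exactly to n.
largest_remainder <- function(n, props) {
  if (any(props <= 0)) stop("class proportions must be positive")
  raw <- n * props / sum(props)
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Simulate expression cohorts with diffusion-borne class signal
#'
#' Generates discovery and validation expression matrices whose class
#' structure mirrors the model family: each class k receives a shift
#' vector `s_k` (the `effect_size` on that class's seed proteins) that
#' acts partly directly and partly through network neighbors,
#' `m_k = signal_theta * (I + mu_true L)^{-1} s_k + (1 - signal_theta) * s_k`;
#' samples are `m_k` plus i.i.d. Gaussian noise. The diffused component
#' is smooth over the graph while the noise is not, which is the
#' structure the network-aware classifier exploits, and the true mixing
#' ratio `signal_theta` is the quantity the combining-ratio sweep should
#' recover.
#'
#' Class sizes follow `class_props` by largest-remainder rounding, and
#' both cohorts are drawn i.i.d. from the same generative law.
#'
#' @param net A `ppi_network` (e.g. from [simulate_ppi_network()]).
#' @param n_discovery,n_validation Cohort sizes. Defaults 271 and 121.
#' @param class_props Named positive class weights (normalized
#'   internally); default the imbalanced three-class cohort
#'   `MCI 191 / AD 58 / VD 22` (roughly 70/21/8 percent).
#' @param seeds_per_class Number of directly shifted proteins per
#'   class; seed sets are disjoint across classes. Default 4.
#' @param effect_size Shift applied to seed proteins, in expression
#'   (NPX-like) units. Default 0.8. `0` gives a null dataset with no
#'   class signal.
#' @param mu_true Diffusion smoothness of the generator. Default 1.
#' @param noise_sd Residual Gaussian standard deviation. Default 1.
#' @param signal_theta Weight of the diffused (network-borne) component
#'   of the class signal, in \[0, 1\]. Default 0.5; `0` is the
#'   generator-mismatch mode where shifts do not act through the
#'   network at all.
#' @param seed Integer seed; output is fully deterministic given it.
#' @return List with `discovery` and `validation` (each `X`, `Y`) and
#'   `truth` (`mu_true`, `seed_proteins` per class, `class_means`,
#'   `effect_size`, `noise_sd`, `signal_theta`).
#' @export
simulate_expression <- function(net, n_discovery = 271, n_validation = 121,
                                class_props = c(MCI = 191, AD = 58,
                                                VD = 22) / 271,
                                seeds_per_class = 4, effect_size = 0.8,
                                mu_true = 1, noise_sd = 1,
                                signal_theta = 0.5, seed = 1) {
  stopifnot(inherits(net, "ppi_network"))
  if (mu_true < 0) stop("mu_true must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  classes <- names(class_props)
  if (is.null(classes)) stop("class_props must be named")
  c <- length(classes)
  p <- length(net$proteins)
  if (c * seeds_per_class > p) {
    stop("need c * seeds_per_class <= p to keep seed sets disjoint")
  }
  set.seed(as.integer(seed))

  # seed proteins drawn degree-weighted: differential biomarkers tend to
  # be pathway-central, and well-connected seeds are what lets the shift
  # act through network neighbors
  deg <- rowSums(net$W > 0)
  picks <- sample(net$proteins, c * seeds_per_class, prob = deg + 1)
  seed_proteins <- split(picks, rep(classes, each = seeds_per_class))
  seed_proteins <- seed_proteins[classes]

  L <- graph_laplacian(net)
  S <- matrix(0, p, c, dimnames = list(net$proteins, classes))
  for (k in classes) S[seed_proteins[[k]], k] <- effect_size
  if (signal_theta < 0 || signal_theta > 1) {
    stop("signal_theta must be in [0, 1]")
  }
  Sdiff <- if (mu_true > 0) phi_solve(L, mu_true, S) else S
  M <- signal_theta * Sdiff + (1 - signal_theta) * S
  dimnames(M) <- dimnames(S)

  draw_cohort <- function(n, prefix) {
    counts <- largest_remainder(n, class_props)
    lab <- sample(rep(classes, counts))
    ids <- sprintf("%s%03d", prefix, seq_len(n))
    X <- M[, lab, drop = FALSE] +
      matrix(stats::rnorm(p * n, sd = noise_sd), p, n)
    dimnames(X) <- list(net$proteins, ids)
    Y <- one_hot_labels(lab, classes)
    colnames(Y) <- ids
    list(X = X, Y = Y)
  }
  discovery <- draw_cohort(n_discovery, "D")
  validation <- draw_cohort(n_validation, "V")

  list(discovery = discovery, validation = validation,
       truth = list(mu_true = mu_true, seed_proteins = seed_proteins,
                    class_means = M, effect_size = effect_size,
                    noise_sd = noise_sd, signal_theta = signal_theta))
}

#' Write a simulated dataset as plain-text fixtures
#'
#' Emits the files the pipeline readers consume: STRING-style edge list
#' (scores on the 0--1000 scale), discovery/validation expression and
#' label TSVs, and a `truth.json` with the generative ground truth.
#'
#' @param dir Output directory (created if needed).
#' @param network A `ppi_network`.
#' @param sim Output of [simulate_expression()].
#' @return Named character vector of the written paths, invisibly.
#' @export
write_gpn_fixture <- function(dir, network, sim) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  W <- network$W
  idx <- which(W > 0 & upper.tri(W), arr.ind = TRUE)
  edges <- data.frame(protein1 = network$proteins[idx[, 1]],
                      protein2 = network$proteins[idx[, 2]],
                      combined_score = format(W[idx] * 1000, digits = 17,
                                              scientific = FALSE,
                                              trim = TRUE))
  paths <- c(
    ppi = file.path(dir, "ppi_edges.tsv"),
    expression_discovery = file.path(dir, "expression_discovery.tsv"),
    labels_discovery = file.path(dir, "labels_discovery.tsv"),
    expression_validation = file.path(dir, "expression_validation.tsv"),
    labels_validation = file.path(dir, "labels_validation.tsv"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.table(edges, paths[["ppi"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_expression(sim$discovery$X, paths[["expression_discovery"]])
  write_labels(sim$discovery$Y, paths[["labels_discovery"]])
  write_expression(sim$validation$X, paths[["expression_validation"]])
  write_labels(sim$validation$Y, paths[["labels_validation"]])
  truth <- sim$truth
  truth$class_means <- NULL                     # derivable from the rest
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
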