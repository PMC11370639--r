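#' Pipeline runners
#'
#' Thin orchestration over the package functions, matching the
#' command-line subcommands (`simulate`, `netstats`, `train`, `predict`,
#' `eval`, `sweep`). Each runner reads/writes the plain-text formats of
#' the IO layer, logs the seed and package version, and returns its main
#' artifact invisibly.
#'
#' @name gpn_pipeline
NULL

gpn_log <- function(outdir, event, seed = NULL) {
  line <- sprintf("[%s] %s | gpnet %s%s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), event,
                  as.character(utils::packageVersion("gpnet")),
                  if (is.null(seed)) "" else paste0(" | seed ", seed))
  cat(line, "\n", sep = "", file = file.path(outdir, "run.log"),
      append = TRUE)
}

load_aligned_inputs <- function(expression, ppi, labels = NULL,
                                class_order = NULL,
                                missing_policy = "zero_row") {
  X <- read_expression(expression)
  edges <- read_ppi_edges(ppi)
  net <- ppi_network(edges, rownames(X), missing_policy = missing_policy)
  out <- list(X = X, net = net, L = graph_laplacian(net))
  if (!is.null(labels)) {
    out$Y <- read_labels(labels, colnames(X), class_order = class_order)
  }
  out
}

#' @rdname gpn_pipeline
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed.
#' @param ... Passed on to [simulate_ppi_network()] /
#'   [simulate_expression()] (run_simulate), [gpn_train()] (run_train)
#'   or [parameter_sweep()] (run_sweep).
#' @export
run_simulate <- function(outdir, seed = 1, ...) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  dots <- list(...)
  net_args <- dots[names(dots) %in% names(formals(simulate_ppi_network))]
  exp_args <- dots[names(dots) %in% names(formals(simulate_expression))]
  simnet <- do.call(simulate_ppi_network, c(list(seed = seed), net_args))
  sim <- do.call(simulate_expression,
                 c(list(net = simnet$network, seed = seed + 1L), exp_args))
  paths <- write_gpn_fixture(outdir, simnet$network, sim)
  gpn_log(outdir, "simulate", seed)
  invisible(list(network = simnet, sim = sim, paths = paths))
}

#' @rdname gpn_pipeline
#' @param expression,ppi,labels Input TSV paths.
#' @param groups_file Optional two-column TSV (protein, group) for
#'   intra/inter-group statistics.
#' @export
run_netstats <- function(expression, ppi, outdir, groups_file = NULL) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  inp <- load_aligned_inputs(expression, ppi)
  groups <- NULL
  if (!is.null(groups_file)) {
    gdf <- utils::read.delim(groups_file, header = FALSE,
                             colClasses = "character")
    groups <- stats::setNames(gdf[[2L]], gdf[[1L]])
  }
  stats <- network_stats(inp$net, groups)
  write_network_stats(stats, file.path(outdir, "network_stats.json"))
  gpn_log(outdir, "netstats")
  invisible(stats)
}

#' @rdname gpn_pipeline
#' @export
run_train <- function(expression, labels, ppi, outdir, seed = 1, ...) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  inp <- load_aligned_inputs(expression, ppi, labels)
  model <- gpn_train(inp$X, inp$L, inp$Y, seed = seed, ...)
  write_gpn(model, file.path(outdir, "model.json"))
  utils::write.table(
    data.frame(epoch = seq_along(model$loss_history),
               loss = model$loss_history),
    file.path(outdir, "training_log.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  gpn_log(outdir, "train", seed)
  invisible(model)
}

#' @rdname gpn_pipeline
#' @param model_file Path to a model JSON written by [write_gpn()].
#' @export
run_predict <- function(expression, ppi, model_file, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  model <- read_gpn(model_file)
  X <- read_expression(expression)
  if (!identical(rownames(X), model$proteins)) {
    missing <- setdiff(model$proteins, rownames(X))
    extra <- setdiff(rownames(X), model$proteins)
    stop("expression proteins do not match the model; missing: ",
         paste(missing, collapse = ", "), "; extra: ",
         paste(extra, collapse = ", "))
  }
  edges <- read_ppi_edges(ppi)
  net <- ppi_network(edges, model$proteins)
  pred <- predict(model, X, graph_laplacian(net))
  df <- data.frame(sample = colnames(X), t(round(pred$P, 6L)),
                   predicted = pred$labels, check.names = FALSE)
  utils::write.table(df, file.path(outdir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gpn_log(outdir, "predict")
  invisible(pred)
}

#' @rdname gpn_pipeline
#' @param predictions Path to a predictions TSV from [run_predict()].
#' @export
run_eval <- function(predictions, labels, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  df <- utils::read.delim(predictions, header = TRUE, check.names = FALSE)
  classes <- setdiff(colnames(df), c("sample", "predicted"))
  P <- t(as.matrix(df[, classes, drop = FALSE]))
  colnames(P) <- df$sample
  Y <- read_labels(labels, df$sample, class_order = classes)
  metrics <- metric_report(P, Y)
  write_metric_report(metrics, file.path(outdir, "metrics.json"))
  gpn_log(outdir, "eval")
  invisible(metrics)
}

#' @rdname gpn_pipeline
#' @param expression_eval,labels_eval Evaluation-split inputs for the
#'   parameter sweep.
#' @export
run_sweep <- function(expression, labels, ppi, expression_eval,
                      labels_eval, outdir, seed = 1, ...) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  inp <- load_aligned_inputs(expression, ppi, labels)
  X_eval <- read_expression(expression_eval)
  if (!identical(rownames(X_eval), rownames(inp$X))) {
    stop("evaluation expression proteins differ from the discovery split")
  }
  Y_eval <- read_labels(labels_eval, colnames(X_eval),
                        class_order = rownames(inp$Y))
  sweep <- parameter_sweep(inp$X, inp$L, inp$Y, X_eval, Y_eval, ...)
  write_sweep(sweep, file.path(outdir, "sweep.tsv"))
  gpn_log(outdir, "sweep", seed)
  invisible(sweep)
}
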