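#' Read a STRING-style PPI edge list
#'
#' Parses a tab-separated edge list with columns `protein1`, `protein2`
#' and `combined_score` (header optional, `#` comment lines skipped).
#' Undirected duplicates (including reciprocal rows) are collapsed keeping
#' the maximum weight, and self-loops are dropped.
#'
#' @param path Path to the TSV file.
#' @param score_scale `"raw_0_1000"` for STRING combined scores in
#'   0--1000 (divided by 1000 on load), or `"unit"` for weights already
#'   in \[0, 1\].
#' @return A data frame with columns `protein1`, `protein2`, `weight`,
#'   one row per undirected edge, weights in \[0, 1\].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("protein1\tprotein2\tcombined_score",
#'              "A\tB\t330", "B\tA\t700", "A\tA\t900"), tf)
#' read_ppi_edges(tf)  # single edge A-B with weight 0.7
#' @export
read_ppi_edges <- function(path, score_scale = c("raw_0_1000", "unit")) {
  score_scale <- match.arg(score_scale)
  if (!file.exists(path)) {
    stop("PPI edge file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(protein1 = character(), protein2 = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # tolerate whitespace-delimited exports
  if (length(fields[[1]]) < 3L) {
    fields <- strsplit(lines, "\\s+")
  }
  # header row: third column is not numeric
  first <- fields[[1]]
  if (length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3L])))) {
    fields <- fields[-1L]
    line_no <- line_no[-1L]
  }
  if (length(fields) == 0L) {
    return(data.frame(protein1 = character(), protein2 = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- line_no[which(nf < 3L)[1L]]
    stop("malformed PPI edge row at line ", bad, ": fewer than 3 columns")
  }
  p1 <- vapply(fields, `[[`, character(1), 1L)
  p2 <- vapply(fields, `[[`, character(1), 2L)
  sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(sc)) {
    bad <- line_no[which(is.na(sc))[1L]]
    stop("malformed PPI edge row at line ", bad, ": non-numeric score")
  }
  if (any(sc < 0)) {
    bad <- line_no[which(sc < 0)[1L]]
    stop("negative interaction score at line ", bad)
  }
  w <- if (score_scale == "raw_0_1000") sc / 1000 else sc
  if (any(w > 1)) {
    bad <- line_no[which(w > 1)[1L]]
    stop("edge weight above 1 after scaling at line ", bad,
         "; check score_scale")
  }
  self <- p1 == p2
  p1 <- p1[!self]; p2 <- p2[!self]; w <- w[!self]
  if (length(w) == 0L) {
    return(data.frame(protein1 = character(), protein2 = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  # canonical unordered pair, dedup by max weight
  a <- pmin(p1, p2)
  b <- pmax(p1, p2)
  key <- paste(a, b, sep = "\r")
  wmax <- tapply(w, key, max)
  keys <- names(wmax)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    protein1 = vapply(parts, `[[`, character(1), 1L),
    protein2 = vapply(parts, `[[`, character(1), 2L),
    weight   = as.numeric(wmax),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$protein1, out$protein2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a weighted PPI adjacency aligned to a protein order
#'
#' Restricts an edge list to the proteins of the expression matrix and
#' returns a symmetric weighted adjacency in that exact order. Edges with
#' an endpoint outside `protein_order` are discarded.
#'
#' @param edges Data frame as returned by [read_ppi_edges()].
#' @param protein_order Character vector of unique protein symbols, the
#'   row order of the paired expression matrix.
#' @param missing_policy `"zero_row"` keeps proteins with no retained
#'   edge as isolated nodes (all-zero row/column); `"error"` fails if any
#'   protein ends up with no edge.
#' @return A `ppi_network` object: list with `proteins` and the p x p
#'   symmetric weight matrix `W` (zero diagonal, entries in \[0, 1\]).
#' @export
ppi_network <- function(edges, protein_order,
                        missing_policy = c("zero_row", "error")) {
  missing_policy <- match.arg(missing_policy)
  protein_order <- as.character(protein_order)
  if (anyDuplicated(protein_order)) {
    stop("duplicated protein symbols in protein_order: ",
         paste(unique(protein_order[duplicated(protein_order)]),
               collapse = ", "))
  }
  p <- length(protein_order)
  if (p < 2L) stop("need at least 2 proteins, got ", p)
  W <- matrix(0, p, p, dimnames = list(protein_order, protein_order))
  if (nrow(edges) > 0L) {
    i <- match(edges$protein1, protein_order)
    j <- match(edges$protein2, protein_order)
    keep <- !is.na(i) & !is.na(j)
    n_drop <- sum(!keep)
    if (n_drop > 0L) {
      message(n_drop, " edge(s) dropped: endpoint(s) outside protein order")
    }
    if (any(keep)) {
      W[cbind(i[keep], j[keep])] <- edges$weight[keep]
      W[cbind(j[keep], i[keep])] <- edges$weight[keep]
    }
  }
  if (missing_policy == "error") {
    deg <- rowSums(W > 0)
    if (any(deg == 0)) {
      stop("protein(s) with no PPI edge: ",
           paste(protein_order[deg == 0], collapse = ", "))
    }
  }
  structure(list(proteins = protein_order, W = W), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  ne <- sum(x$W[upper.tri(x$W)] > 0)
  cat("ppi_network:", length(x$proteins), "proteins,", ne, "edges\n")
  invisible(x)
}

#' Unnormalized graph Laplacian of a PPI network
#'
#' Returns `L = D - W` where `D` is the diagonal matrix of weighted row
#' sums (weighted degrees). For symmetric nonnegative `W` this Laplacian
#' is positive semidefinite with row sums zero, which makes the
#' propagation operator `I + mu * L` positive definite for any mu >= 0.
#'
#' @param net A `ppi_network`.
#' @return Symmetric p x p matrix with protein dimnames.
#' @export
graph_laplacian <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  W <- net$W
  L <- diag(rowSums(W), nrow = nrow(W)) - W
  dimnames(L) <- dimnames(W)
  L
}

#' Descriptive statistics of a PPI network
#'
#' Node/edge counts, density relative to the complete graph, per-protein
#' degrees (count of positive-weight incident edges) and, when a
#' two-group node annotation is supplied (e.g. up- vs down-regulated
#' biomarkers), intra- and inter-group edge counts and mean edge weights.
#'
#' @param net A `ppi_network`.
#' @param groups Optional named character vector mapping every protein to
#'   a group label.
#' @return A `network_stats` list: `n_nodes`, `n_edges`, `density`,
#'   `degree_by_node`, and `group_stats` (NULL unless `groups` given)
#'   with `intra`/`inter` each holding `count` and `mean_weight`.
#' @export
network_stats <- function(net, groups = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  W <- net$W
  p <- nrow(W)
  up <- upper.tri(W)
  has_edge <- W > 0 & up
  n_edges <- sum(has_edge)
  density <- n_edges / (p * (p - 1) / 2)
  degree <- as.integer(rowSums(W > 0))
  names(degree) <- net$proteins
  group_stats <- NULL
  if (!is.null(groups)) {
    missing <- setdiff(net$proteins, names(groups))
    if (length(missing) > 0L) {
      stop("groups does not cover protein(s): ",
           paste(missing, collapse = ", "))
    }
    g <- groups[net$proteins]
    same <- outer(g, g, "==")
    intra_idx <- has_edge & same
    inter_idx <- has_edge & !same
    group_stats <- list(
      intra = list(count = sum(intra_idx),
                   mean_weight = if (any(intra_idx)) mean(W[intra_idx]) else NA_real_),
      inter = list(count = sum(inter_idx),
                   mean_weight = if (any(inter_idx)) mean(W[inter_idx]) else NA_real_)
    )
  }
  structure(list(n_nodes = p, n_edges = n_edges, density = density,
                 degree_by_node = degree, group_stats = group_stats),
            class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("network: %d nodes, %d edges, density %.2f%%\n",
              x$n_nodes, x$n_edges, 100 * x$density))
  if (!is.null(x$group_stats)) {
    gs <- x$group_stats
    cat(sprintf("  intra-group: %d edges, mean weight %.2f\n",
                gs$intra$count, gs$intra$mean_weight))
    cat(sprintf("  inter-group: %d edges, mean weight %.2f\n",
                gs$inter$count, gs$inter$mean_weight))
  }
  invisible(x)
}

#' Serialize network statistics to JSON
#'
#' @param stats A `network_stats` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_stats <- function(stats, path) {
  stopifnot(inherits(stats, "network_stats"))
  obj <- list(n_nodes = stats$n_nodes, n_edges = stats$n_edges,
              density = stats$density,
              degrees = as.list(stats$degree_by_node))
  if (!is.null(stats$group_stats)) {
    obj$intra <- stats$group_stats$intra
    obj$inter <- stats$group_stats$inter
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
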