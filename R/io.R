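#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids, a first column of protein
#' symbols and numeric expression values (e.g. Olink NPX) in the
#' remaining cells. Duplicated proteins, missing cells and non-numeric
#' cells are hard errors with coordinates: imputation and filtering are
#' upstream of this package.
#'
#' @param path TSV path.
#' @return Numeric matrix, proteins x samples, with dimnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", sep = "\t")
  if (ncol(df) < 2L) stop("expression file needs a protein column and at least one sample column")
  proteins <- df[[1L]]
  dup <- proteins[duplicated(proteins)]
  if (length(dup) > 0L) {
    stop("duplicated protein symbol(s): ", paste(unique(dup), collapse = ", "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2L, as.numeric))
  num <- matrix(num, nrow = nrow(vals),
                dimnames = list(proteins, colnames(vals)))
  bad <- which(is.na(num) | vals == "", arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("missing or non-numeric expression value for protein '",
         proteins[bad[1L, 1L]], "', sample '", colnames(vals)[bad[1L, 2L]],
         "'")
  }
  num
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]; full double precision.
#'
#' @param X Numeric matrix with protein rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(X, path) {
  X <- as.matrix(X)
  df <- data.frame(protein = rownames(X),
                   apply(X, 2L, format, digits = 17, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("protein", colnames(X))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' One-hot encode class labels
#'
#' @param labels Character vector of class labels, one per sample.
#' @param class_order Optional fixed class order; default order of
#'   first appearance.
#' @return `{0,1}` matrix, classes x samples, each column summing to 1.
#' @export
one_hot_labels <- function(labels, class_order = NULL) {
  ids <- names(labels)
  labels <- as.character(labels)
  if (is.null(class_order)) class_order <- unique(labels)
  unknown <- setdiff(labels, class_order)
  if (length(unknown) > 0L) {
    stop("label(s) outside the fixed class order: ",
         paste(unique(unknown), collapse = ", "))
  }
  Y <- vapply(labels, function(l) as.numeric(class_order == l),
              numeric(length(class_order)))
  matrix(Y, nrow = length(class_order),
         dimnames = list(class_order, ids))
}

#' Read a sample label table and align it to an expression matrix
#'
#' Expects a two-column TSV `sample` / `class` (header optional). The
#' returned one-hot matrix follows the sample order of `samples`;
#' samples with no label are an error, labelled samples absent from the
#' expression data are ignored with a warning.
#'
#' @param path TSV path.
#' @param samples Character vector of sample ids in expression order.
#' @param class_order Optional fixed class order; default first
#'   appearance in file order.
#' @return One-hot matrix, classes x samples, with dimnames.
#' @export
read_labels <- function(path, samples, class_order = NULL) {
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, check.names = FALSE,
                          colClasses = "character", sep = "\t")
  if (ncol(df) < 2L) stop("label file needs sample and class columns")
  # drop a header row if present (second field not matching any sample
  # is not reliable; detect by first field being the literal 'sample')
  if (tolower(df[1L, 1L]) %in% c("sample", "sample_id", "id")) {
    df <- df[-1L, , drop = FALSE]
  }
  ids <- df[[1L]]; cls <- df[[2L]]
  if (anyDuplicated(ids)) {
    stop("duplicated sample id(s) in label file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  missing <- setdiff(samples, ids)
  if (length(missing) > 0L) {
    stop("sample(s) missing from label file: ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(ids, samples)
  if (length(extra) > 0L) {
    warning(length(extra), " labelled sample(s) absent from expression",
            " data ignored: ", paste(utils::head(extra, 5L), collapse = ", "),
            if (length(extra) > 5L) ", ..." else "")
  }
  keep <- match(samples, ids)
  labels <- stats::setNames(cls[keep], samples)
  if (is.null(class_order)) class_order <- unique(cls)
  one_hot_labels(labels, class_order)
}

#' Write one-hot labels as a sample/class TSV
#'
#' @param Y One-hot matrix with class rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(Y, path) {
  Y <- as.matrix(Y)
  lab <- rownames(Y)[apply(Y, 2L, which.max)]
  df <- data.frame(sample = colnames(Y), class = lab,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
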