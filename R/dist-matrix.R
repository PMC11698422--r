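#' Construct and validate a labelled distance matrix
#'
#' All clustering entry points in the package consume a plain symmetric
#' numeric matrix with zero diagonal and unique dimnames.  `dist_matrix()`
#' validates (and symmetrizes trivially asymmetric input caused by floating
#' point) and returns the matrix; it is the single choke point for the
#' invariants every builder relies on.
#'
#' @param d square numeric matrix, or a [stats::dist] object.
#' @param labels optional character vector of labels; defaults to existing
#'   dimnames.
#' @return symmetric numeric matrix with `labels` as both dimnames.
#' @export
dist_matrix <- function(d, labels = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d)) stop("'d' must be a numeric matrix")
  if (nrow(d) != ncol(d)) stop("'d' must be square")
  if (is.null(labels)) labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("S", seq_len(nrow(d)))
  if (length(labels) != nrow(d)) stop("label length does not match matrix")
  if (anyDuplicated(labels)) stop("duplicate labels in distance matrix")
  if (any(!is.finite(d))) stop("non-finite entries in distance matrix")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  if (any(d < 0)) stop("negative distances")
  dimnames(d) <- list(labels, labels)
  d
}

#' Read / write a labelled square distance matrix as TSV
#'
#' Square layout with a header row and a leading label column.
#'
#' @param path file path.
#' @return `read_dist_tsv` returns a validated matrix; `write_dist_tsv`
#'   returns `path` invisibly.
#' @export
read_dist_tsv <- function(path) {
  x <- read.delim(path, row.names = 1, check.names = FALSE)
  dist_matrix(as.matrix(x))
}

#' @rdname read_dist_tsv
#' @param d distance matrix as from [dist_matrix()].
#' @export
write_dist_tsv <- function(d, path) {
  d <- dist_matrix(d)
  df <- data.frame(label = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
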