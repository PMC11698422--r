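#' Trinarize a count matrix against per-sample MED +/- SD thresholds
#'
#' Each sample's counts are reduced to three states by comparison with that
#' sample's own global count distribution: a gene scores `-1` when its
#' count is strictly below `MED - SD`, `+1` when strictly above
#' `MED + SD`, and `0` otherwise (values exactly on a threshold are `0`).
#' `MED` is the median and `SD` the standard deviation of all counts in
#' the sample; `sd_type` selects the sample (`n - 1` denominator, default)
#' or population (`n`) estimator, recorded in the result.
#'
#' A constant sample (`SD = 0`) degenerates to sign-of-deviation coding
#' (every count differing from the median gets a non-zero state); a
#' warning is raised because such a sample carries no scale information.
#'
#' @param counts numeric genes x samples matrix, non-negative, with
#'   dimnames; at least 2 genes.
#' @param sd_type `"sample"` or `"population"`.
#' @return object of class `"trinary_matrix"`: list with `values`
#'   (genes x samples matrix in \{-1, 0, 1\}), `med`, `sd` (per-sample),
#'   and `sd_type`.
#' @examples
#' m <- matrix(c(0, 5, 10, 5, 5), ncol = 1,
#'             dimnames = list(paste0("g", 1:5), "s1"))
#' trinarize(m)$values[, 1]   # -1 0 1 0 0
#' @export
trinarize <- function(counts, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("need at least 2 genes per sample")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  med <- apply(counts, 2, median)
  s <- apply(counts, 2, sd)
  if (sd_type == "population")
    s <- s * sqrt((nrow(counts) - 1) / nrow(counts))
  if (any(s == 0))
    warning("constant sample(s) with SD = 0: ",
            paste(colnames(counts)[s == 0], collapse = ", "))
  lo <- sweep(counts, 2, med - s, `<`)
  hi <- sweep(counts, 2, med + s, `>`)
  v <- matrix(0L, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  v[lo] <- -1L
  v[hi] <- 1L
  structure(list(values = v, med = med, sd = s, sd_type = sd_type),
            class = "trinary_matrix")
}

#' @export
print.trinary_matrix <- function(x, ...) {
  cat("Trinary matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples (SD:", x$sd_type, ")\n")
  tab <- apply(x$values, 2, function(col) table(factor(col, c(-1, 0, 1))))
  print(tab)
  invisible(x)
}

#' Three-state distance between trinarized samples
#'
#' Pairwise distances on the \{-1, 0, +1\} alphabet.  The default is the
#' maximum-likelihood distance under a symmetric 3-state substitution
#' model (the 3-state analogue of the Jukes–Cantor correction): with `p`
#' the proportion of genes whose states differ,
#' \deqn{d = -\tfrac{2}{3}\,\ln(1 - \tfrac{3}{2} p),}
#' capped at `d_max` when the correction saturates (`p >= 2/3`) or
#' exceeds the cap.  `method = "p"` returns the raw proportion `p`.
#'
#' @param tm a [trinarize()] result (or a plain genes x samples matrix in
#'   \{-1, 0, 1\}).
#' @param method `"ml3"` (default) or `"p"`.
#' @param d_max cap for saturated ML distances.
#' @return labelled distance matrix.
#' @export
three_state_distance <- function(tm, method = c("ml3", "p"), d_max = 5) {
  method <- match.arg(method)
  v <- if (inherits(tm, "trinary_matrix")) tm$values else as.matrix(tm)
  if (nrow(v) < 1) stop("need at least 1 gene")
  ns <- ncol(v)
  d <- matrix(0, ns, ns, dimnames = list(colnames(v), colnames(v)))
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (j <= i) next
    p <- mean(v[, i] != v[, j])
    dij <- if (method == "p") p
           else if (p >= 2 / 3) d_max
           else min(-(2 / 3) * log(1 - 1.5 * p), d_max)
    d[i, j] <- d[j, i] <- dij
  }
  dist_matrix(d)
}

#' Transcript-derived phylogeny: trinarize, 3-state distance, UPGMA
#'
#' The full transcript channel: [trinarize()] the counts, compute the
#' [three_state_distance()], and cluster with [upgma()].
#'
#' @inheritParams trinarize
#' @inheritParams three_state_distance
#' @param drop_allzero drop genes with zero counts in every sample before
#'   trinarization (by default they are retained; they contribute
#'   concordant states).
#' @return a [stats::dendrogram].
#' @export
build_trinary_tree <- function(counts, method = c("ml3", "p"),
                               sd_type = c("sample", "population"),
                               d_max = 5, drop_allzero = FALSE) {
  counts <- as.matrix(counts)
  if (drop_allzero) counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  upgma(three_state_distance(trinarize(counts, sd_type = sd_type),
                             method = method, d_max = d_max))
}
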