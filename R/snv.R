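#' Identity-by-state distance between genotype columns
#'
#' For samples `i`, `j` and the sites where both have a non-missing
#' dosage, the per-site identity by state is `(2 - |g_i - g_j|) / 2`
#' (1 for identical dosages, 0.5 for het vs hom, 0 for opposite
#' homozygotes); `IBS(i, j)` is its mean and the returned distance is
#' `1 - IBS`.  Missing data are handled pairwise-complete; a pair with no
#' shared non-missing site is an error naming the pair.
#'
#' @param gm sites x samples matrix of allele dosages in \{0, 1, 2\} with
#'   `NA` for missing; at least 2 samples.
#' @return labelled distance matrix in `[0, 1]`.
#' @examples
#' g <- cbind(a = c(1, 0), b = c(1, 2))  # sites: (het,het), (0,2)
#' ibs_matrix(g)["a", "b"]               # (1 + 0)/2 -> distance 0.5
#' @export
ibs_matrix <- function(gm) {
  gm <- as.matrix(gm)
  if (ncol(gm) < 2) stop("need at least 2 samples")
  if (any(!(gm %in% c(0, 1, 2, NA)))) stop("dosages must be 0, 1, 2 or NA")
  if (is.null(colnames(gm))) colnames(gm) <- paste0("S", seq_len(ncol(gm)))
  ns <- ncol(gm)
  d <- matrix(0, ns, ns, dimnames = list(colnames(gm), colnames(gm)))
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (j <= i) next
    ok <- !is.na(gm[, i]) & !is.na(gm[, j])
    if (!any(ok))
      stop("samples '", colnames(gm)[i], "' and '", colnames(gm)[j],
           "' share no non-missing site")
    ibs <- mean((2 - abs(gm[ok, i] - gm[ok, j])) / 2)
    d[i, j] <- d[j, i] <- 1 - ibs
  }
  dist_matrix(d)
}

#' Depth-gated presence/absence divergence from RNA variant reads
#'
#' A variant is called present in a cell at a site when coverage reaches
#' `min_depth` and the alt-allele fraction reaches `alt_threshold`.  The
#' divergence between two cells is the proportion of sites covered to
#' `min_depth` in *both* cells at which the presence calls differ.  This
#' is a deliberately simple, depth-aware surrogate for model-based
#' genetic-divergence estimators on sparse single-cell RNA variant data.
#'
#' @param alt,total sites x cells integer matrices of alt and total read
#'   counts (`alt <= total`).
#' @param min_depth minimum total reads for a site to be evaluable in a
#'   cell.
#' @param alt_threshold minimum alt fraction for a presence call.
#' @return labelled distance matrix in `[0, 1]`.
#' @export
rna_divergence <- function(alt, total, min_depth = 3, alt_threshold = 0.2) {
  alt <- as.matrix(alt); total <- as.matrix(total)
  stopifnot(all(dim(alt) == dim(total)))
  if (any(alt > total)) stop("alt reads exceed total reads")
  if (any(alt < 0) || any(total < 0)) stop("negative read counts")
  if (is.null(colnames(total))) colnames(total) <- paste0("C", seq_len(ncol(total)))
  covered <- total >= min_depth
  present <- covered & (alt / pmax(total, 1) >= alt_threshold)
  ns <- ncol(total)
  labs <- colnames(total)
  d <- matrix(0, ns, ns, dimnames = list(labs, labs))
  bad <- character(0)
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (j <= i) next
    ok <- covered[, i] & covered[, j]
    if (!any(ok)) {
      bad <- c(bad, paste0(labs[i], "/", labs[j]))
      next
    }
    d[i, j] <- d[j, i] <- mean(present[ok, i] != present[ok, j])
  }
  if (length(bad))
    stop("no co-covered sites at min_depth = ", min_depth,
         " for pair(s): ", paste(bad, collapse = ", "))
  dist_matrix(d)
}

#' Cluster an SNV-channel distance matrix into a dendrogram
#'
#' Convenience wrapper: `ward.D` is the conventional linkage for the
#' RNA-derived divergence channel, average linkage (or [upgma()]) for the
#' identity-by-state channel.
#'
#' @param dm distance matrix from [ibs_matrix()] or [rna_divergence()].
#' @param linkage `"upgma"`, `"average"`, `"complete"` or `"ward.D"`.
#' @return a [stats::dendrogram].
#' @export
build_snv_tree <- function(dm, linkage = c("average", "upgma", "complete",
                                           "ward.D")) {
  linkage <- match.arg(linkage)
  if (linkage == "upgma") upgma(dm) else hclust_tree(dm, linkage)
}
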