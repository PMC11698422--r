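#' Deterministic agglomerative clustering engines
#'
#' Agglomerative hierarchical clustering with the classical Lance--Williams
#' update rules and a fully deterministic tie-break: when several cluster
#' pairs attain the minimal merge criterion, the pair whose sorted pair of
#' representative labels (the lexicographically smallest member label of
#' each cluster) is smallest is merged.  This makes every tree a pure
#' function of the labelled distance matrix, independent of row order —
#' unlike `stats::hclust`, whose result depends on input ordering under
#' ties.  On tie-free input the merge heights and topology agree with
#' `stats::hclust` for the same method.
#'
#' Height conventions (fixed, relied on throughout the package):
#' * `upgma()`: node height = average-linkage merge distance / 2, so the
#'   tree is ultrametric and [cophenetic_dist()] (which doubles heights)
#'   returns the merge distances themselves;
#' * `hclust_tree()` with `average`, `complete` or `ward.D`: node height =
#'   the raw merge criterion, matching `stats::hclust`.
#'
#' @param dm labelled distance matrix (see [dist_matrix()]).
#' @param linkage one of `"average"`, `"complete"`, `"ward.D"`.
#' @return a binary [stats::dendrogram] with leaves at height 0.
#' @examples
#' d <- dist_matrix(matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'                  dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
#' t <- upgma(d)            # A,B join at height 1; C joins at height 2
#' cophenetic_dist(t)       # recovers d exactly (d is ultrametric)
#' @export
upgma <- function(dm) {
  fit <- agglomerate(dist_matrix(dm), "average")
  fit$height <- fit$height / 2
  as.dendrogram(fit)
}

#' @rdname upgma
#' @export
hclust_tree <- function(dm, linkage = c("average", "complete", "ward.D")) {
  linkage <- match.arg(linkage)
  as.dendrogram(agglomerate(dist_matrix(dm), linkage))
}

# Core engine: returns an "hclust" object (merge/height/order/labels).
# Ties resolved by lexicographically smallest sorted representative-label
# pair; within a merge row the cluster with the smaller representative is
# the left child.
agglomerate <- function(d, method) {
  labels <- rownames(d)
  n <- length(labels)
  if (n < 2) stop("need at least 2 labels to cluster")
  upd <- switch(method,
    average  = function(dik, djk, ni, nj, nk, dij)
      (ni * dik + nj * djk) / (ni + nj),
    complete = function(dik, djk, ni, nj, nk, dij) pmax(dik, djk),
    ward.D   = function(dik, djk, ni, nj, nk, dij)
      ((ni + nk) * dik + (nj + nk) * djk - nk * dij) / (ni + nj + nk),
    stop("unknown linkage '", method, "'")
  )
  D <- d
  active <- seq_len(n)
  size <- rep(1L, n)
  rep_lab <- labels                 # representative label per cluster slot
  node_id <- -seq_len(n)            # hclust convention: -i singleton
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  tol <- 1e-12
  for (step in seq_len(n - 1L)) {
    ia <- active
    Dsub <- D[ia, ia, drop = FALSE]
    off <- upper.tri(Dsub)
    mv <- min(Dsub[off])
    cand <- which(off & Dsub <= mv + tol * max(1, abs(mv)), arr.ind = TRUE)
    # candidate pairs as (slot_i, slot_j); pick lexicographically smallest
    # sorted representative-label pair
    ci <- ia[cand[, 1]]; cj <- ia[cand[, 2]]
    lo <- pmin(rep_lab[ci], rep_lab[cj])
    hi <- pmax(rep_lab[ci], rep_lab[cj])
    pick <- order(lo, hi)[1L]
    i <- ci[pick]; j <- cj[pick]
    if (rep_lab[j] < rep_lab[i]) { tmp <- i; i <- j; j <- tmp }
    height[step] <- D[i, j]
    merge[step, ] <- c(node_id[i], node_id[j])
    ks <- setdiff(active, c(i, j))
    if (length(ks)) {
      D[i, ks] <- upd(D[i, ks], D[j, ks], size[i], size[j], size[ks], D[i, j])
      D[ks, i] <- D[i, ks]
    }
    size[i] <- size[i] + size[j]
    node_id[i] <- step
    # rep_lab[i] already the smaller of the two after the swap above
    active <- setdiff(active, j)
  }
  ord <- integer(0)
  walk <- function(id) {
    if (id < 0) ord <<- c(ord, -id)
    else { walk(merge[id, 1]); walk(merge[id, 2]) }
  }
  walk(n - 1L)
  structure(
    list(merge = merge, height = height, order = ord, labels = labels,
         method = method, call = match.call(),
         dist.method = "user-supplied"),
    class = "hclust")
}

#' Cophenetic distances of a dendrogram
#'
#' Returns the matrix `d[i, j] = 2 * height of the lowest common ancestor`
#' of leaves `i` and `j`.  The factor 2 is the package's ultrametric
#' convention: a UPGMA tree (node height = merge distance / 2) therefore
#' maps back to its merge distances, so `cophenetic_dist(upgma(d))`
#' reproduces `d` exactly when `d` is ultrametric.
#'
#' @param t a binary [stats::dendrogram].
#' @return labelled symmetric matrix.
#' @export
cophenetic_dist <- function(t) {
  labs <- labels(t)
  n <- length(labs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  walk <- function(node) {
    if (is.leaf(node)) return(attr(node, "label"))
    l <- walk(node[[1]]); r <- walk(node[[2]])
    d[l, r] <<- 2 * attr(node, "height")
    d[r, l] <<- 2 * attr(node, "height")
    c(l, r)
  }
  walk(t)
  d
}

#' Check the ultrametric three-point condition
#'
#' For every leaf triple the two largest cophenetic distances must be equal
#' (within `tol`).  UPGMA output satisfies this by construction.
#'
#' @param t dendrogram.
#' @param tol absolute tolerance.
#' @return logical scalar.
#' @export
is_ultrametric <- function(t, tol = 1e-9) {
  d <- cophenetic_dist(t)
  n <- nrow(d)
  if (n < 3) return(TRUE)
  for (i in seq_len(n - 2)) for (j in seq(i + 1, n - 1)) for (k in seq(j + 1, n)) {
    v <- sort(c(d[i, j], d[i, k], d[j, k]))
    if (v[3] - v[2] > tol) return(FALSE)
  }
  TRUE
}

#' Leaf labels in display order
#'
#' Thin wrapper over `labels()` returning the left-to-right leaf sequence.
#' @param t dendrogram.
#' @return character vector.
#' @export
leaf_order <- function(t) as.character(labels(t))

#' Swap the children of one internal node
#'
#' Reverses the contiguous block of descendant leaves of `node_path` and
#' changes nothing else.  `node_path` is an integer vector of child indices
#' (1 = left, 2 = right) from the root; `integer(0)` addresses the root.
#' Midpoint attributes are recomputed so the tree still plots correctly.
#'
#' @param t dendrogram.
#' @param node_path integer vector addressing an internal node.
#' @return rotated dendrogram.
#' @export
rotate_node <- function(t, node_path = integer(0)) {
  swap <- function(node, path) {
    if (!length(path)) {
      if (is.leaf(node)) stop("cannot rotate a leaf")
      tmp <- node[[1]]; node[[1]] <- node[[2]]; node[[2]] <- tmp
      return(node)
    }
    node[[path[1]]] <- swap(node[[path[1]]], path[-1])
    node
  }
  fix_midpoints(swap(t, node_path))
}

# Recompute the "midpoint" attribute after structural edits (same recursion
# stats uses internally: mid = (mid_left + members_left + mid_right) / 2).
fix_midpoints <- function(t) {
  walk <- function(node) {
    if (is.leaf(node)) return(node)
    node[[1]] <- walk(node[[1]]); node[[2]] <- walk(node[[2]])
    ml <- if (is.leaf(node[[1]])) 0 else attr(node[[1]], "midpoint")
    mr <- if (is.leaf(node[[2]])) 0 else attr(node[[2]], "midpoint")
    nl <- attr(node[[1]], "members")
    attr(node, "midpoint") <- (ml + nl + mr) / 2
    node
  }
  walk(t)
}
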