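# Independent oracles and fixture builders used across the suite.

# Naive O(n^3) agglomerative oracle: recomputes the cluster-pair linkage
# from the ORIGINAL distance matrix at every round (no Lance-Williams
# recurrence), same lexicographic tie-break as the package engine.
# Returns the cophenetic matrix of merge criteria.
naive_linkage_coph <- function(d, method = c("average", "complete")) {
  method <- match.arg(method)
  labs <- rownames(d)
  clusters <- as.list(labs)
  coph <- matrix(0, nrow(d), nrow(d), dimnames = dimnames(d))
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      cross <- d[clusters[[i]], clusters[[j]], drop = FALSE]
      v <- if (method == "average") mean(cross) else max(cross)
      key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
      if (is.null(best) || v < best$v - 1e-12 ||
          (v < best$v + 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2]))))
        best <- list(v = v, i = i, j = j, key = key)
    }
    coph[clusters[[best$i]], clusters[[best$j]]] <- best$v
    coph[clusters[[best$j]], clusters[[best$i]]] <- best$v
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  coph
}

random_dist <- function(n, seed) {
  set.seed(seed)
  x <- matrix(runif(n * n), n)
  d <- (x + t(x)) / 2
  diag(d) <- 0
  dimnames(d) <- list(sprintf("s%02d", seq_len(n)), sprintf("s%02d", seq_len(n)))
  d
}

random_tree <- function(n, seed) {
  set.seed(seed)
  x <- matrix(rnorm(3 * n), n)
  rownames(x) <- sprintf("L%02d", seq_len(n))
  upgma(dist_matrix(as.matrix(dist(x))))
}

# caterpillar (ladder) tree over labels lab1 < lab2 < ... via UPGMA on
# d(i, j) = max(i, j)
ladder_tree <- function(labels) {
  n <- length(labels)
  d <- outer(seq_len(n), seq_len(n), pmax)
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  upgma(dist_matrix(d))
}

# mirror: swap children of every internal node -> fully reversed leaf order
reverse_tree <- function(node) {
  rec <- function(nd) {
    if (stats::is.leaf(nd)) return(nd)
    tmp <- rec(nd[[1]]); nd[[1]] <- rec(nd[[2]]); nd[[2]] <- tmp
    nd
  }
  clonotangle:::fix_midpoints(rec(node))
}

# all child-order assignments of a binary dendrogram (2^(n-1) trees)
all_rotations <- function(node) {
  if (stats::is.leaf(node)) return(list(node))
  A <- all_rotations(node[[1]]); B <- all_rotations(node[[2]])
  out <- list()
  for (a in A) for (b in B) for (sw in c(FALSE, TRUE)) {
    nd <- node
    if (sw) { nd[[1]] <- b; nd[[2]] <- a } else { nd[[1]] <- a; nd[[2]] <- b }
    out[[length(out) + 1]] <- nd
  }
  lapply(out, clonotangle:::fix_midpoints)
}

# 12-sample segment bundle engineered to leave exactly 28 discordant
# 1200-bp bins: two 6-sample groups, alternating amplification-in-G1 /
# deletion-in-G2 bins, all other bins diploid everywhere
make_discordant_bundle <- function(n_disc = 28, bin_bp = 1200, n_bins = 40) {
  groups <- rep(c("G1", "G2"), each = 6)
  samples <- sprintf("%s_s%d", groups, rep(1:6, 2))
  disc_bins <- seq(5, 4 + n_disc)
  cn <- matrix(2, n_bins, 12, dimnames = list(NULL, samples))
  # cycle four event patterns so the two group call profiles are
  # uncorrelated (not affine transforms of each other)
  for (i in seq_along(disc_bins)) {
    b <- disc_bins[i]
    switch(1 + (i - 1) %% 4,
           cn[b, groups == "G1"] <- 4,
           cn[b, groups == "G1"] <- 1,
           cn[b, groups == "G2"] <- 4,
           cn[b, groups == "G2"] <- 1)
  }
  seg_list <- setNames(lapply(seq_len(12), function(j) {
    r <- rle(cn[, j])
    ends <- cumsum(r$lengths)
    starts <- c(1, utils::head(ends, -1) + 1)
    data.frame(chrom = "chrA", start = (starts - 1) * bin_bp + 1,
               end = ends * bin_bp, total_cn = r$values)
  }), samples)
  list(seg_list = seg_list, bin_bp = bin_bp,
       chrom_lengths = c(chrA = n_bins * bin_bp), groups = groups,
       samples = samples)
}
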