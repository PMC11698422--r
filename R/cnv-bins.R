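#' Rasterize copy-number segments onto fixed-width genomic bins
#'
#' Each chromosome is tiled from its first base in steps of `bin_bp`
#' (`ceiling(length / bin_bp)` bins; the terminal bin may be short).
#' Internally bins are half-open zero-based intervals `[b, b + bin_bp)`
#' and a bin takes the copy number of the segment containing its midpoint
#' `b + bin_bp/2`; segment coordinates are 1-based inclusive (converted to
#' `[start - 1, end)`).  Bins whose midpoint falls in no segment are `NA`.
#' Overlapping segments within the sample are an error listing the
#' offending rows.
#'
#' @param segments data.frame with columns `chrom`, `start`, `end`,
#'   `total_cn` (1-based inclusive coordinates, numeric CN).
#' @param bin_bp bin width in bp (default 1200).
#' @param chrom_lengths named numeric vector of chromosome lengths; every
#'   segment must lie within its chromosome.
#' @return numeric vector of per-bin CN (NA = uncovered), with a
#'   `"bins"` attribute data.frame (`chrom`, `start`, `end`, 1-based
#'   inclusive).
#' @examples
#' len <- c(chr1 = 3600)
#' seg <- data.frame(chrom = "chr1", start = c(1, 1801),
#'                   end = c(1800, 3600), total_cn = c(3, 2))
#' bin_segments(seg, 1200, len)  # 3, 2, 2 (midpoints 600, 1800, 3000)
#' @export
bin_segments <- function(segments, bin_bp = 1200, chrom_lengths) {
  need <- c("chrom", "start", "end", "total_cn")
  if (!all(need %in% names(segments)))
    stop("segments must have columns ", paste(need, collapse = ", "))
  segments$chrom <- as.character(segments$chrom)
  bad_chr <- setdiff(segments$chrom, names(chrom_lengths))
  if (length(bad_chr)) stop("segments on unknown chromosome(s): ",
                            paste(unique(bad_chr), collapse = ", "))
  if (any(segments$start < 1) ||
      any(segments$end > chrom_lengths[segments$chrom]))
    stop("segment outside chromosome bounds")
  if (any(segments$end < segments$start)) stop("segment end before start")
  # overlap check within each chromosome (1-based inclusive)
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    s <- s[order(s$start), ]
    ov <- which(s$start[-1] <= s$end[-nrow(s)])
    if (length(ov))
      stop("overlapping segments on ", ch, ": ",
           paste(sprintf("%d-%d / %d-%d", s$start[ov], s$end[ov],
                         s$start[ov + 1], s$end[ov + 1]), collapse = "; "))
  }
  bins <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    nb <- ceiling(chrom_lengths[[ch]] / bin_bp)
    data.frame(chrom = ch, start = (seq_len(nb) - 1) * bin_bp + 1,
               end = pmin(seq_len(nb) * bin_bp, chrom_lengths[[ch]]))
  }))
  cn <- rep(NA_real_, nrow(bins))
  mid0 <- (bins$start - 1) + bin_bp / 2      # zero-based midpoint
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    bi <- which(bins$chrom == ch)
    for (r in seq_len(nrow(s))) {
      hit <- bi[mid0[bi] >= s$start[r] - 1 & mid0[bi] < s$end[r]]
      cn[hit] <- s$total_cn[r]
    }
  }
  attr(cn, "bins") <- bins
  cn
}

#' @rdname bin_segments
#' @param seg_list named list of per-sample segment data.frames.
#' @return `bin_segment_matrix`: bins x samples numeric matrix with the
#'   same `"bins"` attribute.
#' @export
bin_segment_matrix <- function(seg_list, bin_bp = 1200, chrom_lengths) {
  if (is.null(names(seg_list)))
    names(seg_list) <- paste0("S", seq_along(seg_list))
  cols <- lapply(seg_list, bin_segments, bin_bp = bin_bp,
                 chrom_lengths = chrom_lengths)
  m <- do.call(cbind, cols)
  colnames(m) <- names(seg_list)
  attr(m, "bins") <- attr(cols[[1]], "bins")
  m
}

#' Threshold binned copy numbers into deletion/neutral/amplification calls
#'
#' Call code `-1` (deletion) when `CN <= del_cn`, `+1` (amplification)
#' when `CN >= amp_cn` (thresholds inclusive), `0` otherwise; `NA`
#' propagates.  The defaults call relative to the diploid baseline of 2.
#'
#' @param cn numeric vector or matrix of binned copy numbers.
#' @param del_cn deletion threshold (call when `CN <= del_cn`).
#' @param amp_cn amplification threshold (call when `CN >= amp_cn`).
#' @return integer calls of the same shape, values in \{-1, 0, 1, NA\}.
#' @export
call_bins <- function(cn, del_cn = 1.5, amp_cn = 2.5) {
  if (del_cn >= amp_cn) stop("del_cn must be below amp_cn")
  out <- cn
  out[] <- ifelse(is.na(cn), NA_integer_,
                  ifelse(cn <= del_cn, -1L, ifelse(cn >= amp_cn, 1L, 0L)))
  out
}

#' Keep only bins with discordant calls across samples
#'
#' Drops every bin that is missing in any sample, then every bin whose
#' calls are identical across all samples (calls shared by all samples
#' carry no phylogenetic signal).  Warns when nothing is retained.
#'
#' @param calls bins x samples call matrix from [call_bins()], optionally
#'   carrying the `"bins"` attribute of [bin_segment_matrix()].
#' @param del_cn,amp_cn,bin_bp provenance recorded in the result.
#' @return object of class `"cn_call_matrix"`: list with `calls` (retained
#'   bins x samples), `bins` (their coordinates, or NULL), `n_dropped_missing`,
#'   `n_dropped_shared` and `provenance`.
#' @export
discordant_matrix <- function(calls, del_cn = 1.5, amp_cn = 2.5,
                              bin_bp = NULL) {
  calls <- as.matrix(calls)
  bins <- attr(calls, "bins")
  complete <- rowSums(is.na(calls)) == 0
  m <- calls[complete, , drop = FALSE]
  disc <- apply(m, 1, function(r) any(r != r[1]))
  out <- m[disc, , drop = FALSE]
  if (nrow(out) == 0)
    warning("no discordant bins: all samples share identical calls")
  structure(list(
    calls = out,
    bins = if (!is.null(bins)) bins[complete, , drop = FALSE][disc, , drop = FALSE],
    n_dropped_missing = sum(!complete),
    n_dropped_shared = sum(!disc),
    provenance = list(bin_bp = bin_bp, del_cn = del_cn, amp_cn = amp_cn)),
    class = "cn_call_matrix")
}

#' @export
print.cn_call_matrix <- function(x, ...) {
  cat("Discordant CN call matrix:", nrow(x$calls), "bins x",
      ncol(x$calls), "samples\n")
  cat("  dropped:", x$n_dropped_missing, "incomplete,",
      x$n_dropped_shared, "shared\n")
  invisible(x)
}

# correlation distance between columns; falls back to Euclidean when any
# column has zero variance (correlation undefined)
.col_dist <- function(m, distance) {
  if (distance == "correlation") {
    if (any(apply(m, 2, sd) == 0)) {
      message("zero-variance sample under correlation distance; ",
              "using Euclidean for this matrix")
      distance <- "euclidean"
    } else {
      return(dist_matrix(1 - cor(m)))
    }
  }
  dist_matrix(as.matrix(dist(t(m))))
}

# leaf-set keys of every internal node of a binary dendrogram
.cluster_keys <- function(t) {
  keys <- character(0)
  walk <- function(node) {
    if (is.leaf(node)) return(attr(node, "label"))
    l <- c(walk(node[[1]]), walk(node[[2]]))
    keys <<- c(keys, paste(sort(l), collapse = "\r"))
    l
  }
  walk(t)
  keys
}

#' Cluster samples on a discordant-call matrix with bootstrap support
#'
#' Builds the base dendrogram from the full call matrix (default:
#' average linkage on correlation distances between sample columns), then
#' resamples the bins (rows) with replacement `n_boot` times, re-clusters
#' each replicate, and annotates every internal node of the base tree with
#' the fraction of replicate trees containing the same leaf set — plain
#' bootstrap proportions.  Replicates in which a sample column has zero
#' variance fall back to Euclidean distance for that replicate.
#'
#' @param m a [discordant_matrix()] result or a bins x samples matrix
#'   with at least 2 rows and 3 samples.
#' @param n_boot number of bootstrap resamples (0 = base tree only).
#' @param linkage linkage method for [hclust_tree()], or `"upgma"`.
#' @param distance `"correlation"` or `"euclidean"`.
#' @param seed RNG seed for the resampling.
#' @return a [stats::dendrogram] whose internal nodes carry a `"support"`
#'   attribute in `[0, 1]` (absent when `n_boot = 0`), also tabulated in
#'   attribute `"support_table"`.
#' @export
bootstrap_tree <- function(m, n_boot = 1000, linkage = "average",
                           distance = c("correlation", "euclidean"),
                           seed = NULL) {
  distance <- match.arg(distance)
  calls <- if (inherits(m, "cn_call_matrix")) m$calls else as.matrix(m)
  if (nrow(calls) < 2) stop("need at least 2 discordant bins")
  if (ncol(calls) < 3) stop("need at least 3 samples")
  build <- function(mm, quiet = TRUE) {
    d <- if (quiet) suppressMessages(.col_dist(mm, distance))
         else .col_dist(mm, distance)
    if (linkage == "upgma") upgma(d) else hclust_tree(d, linkage)
  }
  base <- build(calls, quiet = FALSE)
  if (n_boot <= 0) return(base)
  if (!is.null(seed)) set.seed(seed)
  keys <- .cluster_keys(base)
  hits <- setNames(numeric(length(keys)), keys)
  for (b in seq_len(n_boot)) {
    rows <- sample.int(nrow(calls), replace = TRUE)
    bk <- .cluster_keys(build(calls[rows, , drop = FALSE]))
    inb <- keys %in% bk
    hits[inb] <- hits[inb] + 1
  }
  support <- hits / n_boot
  annotate <- function(node) {
    if (is.leaf(node)) return(node)
    node[[1]] <- annotate(node[[1]]); node[[2]] <- annotate(node[[2]])
    key <- paste(sort(leaf_labels_dend(node)), collapse = "\r")
    attr(node, "support") <- unname(support[key])
    node
  }
  out <- annotate(base)
  tab <- data.frame(leaves = gsub("\r", ",", names(support)),
                    support = unname(support))
  attr(out, "support_table") <- tab
  out
}
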