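#' Pseudo-bulk spot counts into section-level counts
#'
#' Sums spot-level counts within each tissue section, yielding one
#' expression column per section — the standard reduction when the
#' comparison data (e.g. WGS of adjacent sections) are not spatially
#' resolved.
#'
#' @param counts genes x spots count matrix.
#' @param section_of section id per spot: a character vector either named
#'   by spot (matched against `colnames(counts)`) or positionally aligned.
#' @return genes x sections count matrix, section columns in first-seen
#'   order.
#' @export
pseudobulk <- function(counts, section_of) {
  counts <- as.matrix(counts)
  if (!is.null(names(section_of))) {
    miss <- setdiff(colnames(counts), names(section_of))
    if (length(miss)) stop("spots without a section: ",
                           paste(head(miss, 5), collapse = ", "))
    section_of <- section_of[colnames(counts)]
  }
  if (length(section_of) != ncol(counts))
    stop("section_of length does not match spot count")
  secs <- unique(as.character(section_of))
  out <- matrix(0, nrow(counts), length(secs),
                dimnames = list(rownames(counts), secs))
  for (s in secs)
    out[, s] <- rowSums(counts[, section_of == s, drop = FALSE])
  out
}

# truncated centered running mean: at position i, mean over
# [max(1, i-h), min(n, i+h)]
running_mean_trunc <- function(x, w) {
  n <- length(x)
  h <- (w - 1) / 2
  cs <- c(0, cumsum(x))
  lo <- pmax(1, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Expression-inferred copy-number profile (moving-average core)
#'
#' A transparent reimplementation of the averaging core of
#' expression-based CNV inference, without any HMM state calling: the
#' smoothed, centred residual expression along the genome is itself the
#' copy-number signal.  Stages, in order:
#'
#' 1. drop genes with mean raw count `< cutoff` across samples;
#' 2. library-size normalize each sample to the median library size, then
#'    `log2(x + 1)`;
#' 3. subtract the per-gene reference mean — columns named in
#'    `reference_labels` if given, otherwise all samples (the
#'    "no reference group" mode);
#' 4. clamp values to `± cap_sd` global standard deviations;
#' 5. centred moving average of `window` genes within each chromosome
#'    (window truncated at chromosome ends), genes in genomic order;
#' 6. subtract each sample's median (re-centres every profile at 0);
#' 7. denoise: zero every value with `|v| < denoise_sd * SD` of the
#'    stage-6 residuals (skipped when `denoise_sd <= 0`).
#'
#' @param counts genes x samples raw count matrix, rownames = gene ids.
#' @param annotation data.frame with columns `gene`, `chrom`, `start`,
#'   `end` covering all retained genes; genes are processed in
#'   `(chrom, start)` order.
#' @param reference_labels optional character vector of normal/reference
#'   sample names.
#' @param cutoff minimum mean raw count for a gene to be retained.
#' @param window moving-average width in genes; odd, `>= 3`.
#' @param cap_sd clamp width in global standard deviations.
#' @param denoise_sd denoising threshold in residual standard deviations.
#' @return object of class `"icnv_profile"`: list with `scores`
#'   (genes x samples, genomic order), `annotation` (retained genes, same
#'   order) and `params`.
#' @export
infer_cnv_profile <- function(counts, annotation, reference_labels = NULL,
                              cutoff = 0.1, window = 101, cap_sd = 3,
                              denoise_sd = 1.0) {
  counts <- as.matrix(counts)
  if (window < 3 || window %% 2 == 0) stop("'window' must be odd and >= 3")
  need <- c("gene", "chrom", "start", "end")
  if (!all(need %in% names(annotation)))
    stop("annotation must have columns ", paste(need, collapse = ", "))
  miss <- setdiff(rownames(counts), annotation$gene)
  if (length(miss)) stop("genes missing from annotation: ",
                         paste(head(miss, 5), collapse = ", "))
  keep <- rowMeans(counts) >= cutoff
  if (!any(keep)) stop("no genes pass the mean-count cutoff of ", cutoff)
  counts <- counts[keep, , drop = FALSE]
  ann <- annotation[match(rownames(counts), annotation$gene), ]
  ord <- order(chrom_rank(ann$chrom), ann$start)
  ann <- ann[ord, ]
  counts <- counts[ord, , drop = FALSE]
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("sample(s) with zero library size: ",
                              paste(colnames(counts)[libsize == 0], collapse = ", "))
  x <- log2(sweep(counts, 2, median(libsize) / libsize, `*`) + 1)
  ref <- if (is.null(reference_labels)) x
         else {
           bad <- setdiff(reference_labels, colnames(x))
           if (length(bad)) stop("unknown reference samples: ",
                                 paste(bad, collapse = ", "))
           x[, reference_labels, drop = FALSE]
         }
  x <- x - rowMeans(ref)
  s_all <- sd(x)
  if (s_all > 0) x[] <- pmin(pmax(x, -cap_sd * s_all), cap_sd * s_all)
  for (ch in unique(ann$chrom)) {
    idx <- which(ann$chrom == ch)
    w <- min(window, if (length(idx) %% 2 == 1) length(idx) else length(idx) - 1)
    if (w >= 3)
      x[idx, ] <- apply(x[idx, , drop = FALSE], 2, running_mean_trunc, w = w)
  }
  x <- sweep(x, 2, apply(x, 2, median))
  s_res <- sd(x)
  if (denoise_sd > 0 && s_res > 0) x[abs(x) < denoise_sd * s_res] <- 0
  structure(list(scores = x, annotation = ann,
                 params = list(cutoff = cutoff, window = window,
                               cap_sd = cap_sd, denoise_sd = denoise_sd,
                               reference = reference_labels)),
            class = "icnv_profile")
}

#' @export
print.icnv_profile <- function(x, ...) {
  cat("iCNV profile:", nrow(x$scores), "genes x", ncol(x$scores),
      "samples; window =", x$params$window,
      "; nonzero fraction =", round(mean(x$scores != 0), 3), "\n")
  invisible(x)
}

# natural chromosome ordering: numeric where possible, then X, Y, rest
chrom_rank <- function(chrom) {
  ch <- sub("^chr", "", as.character(chrom))
  r <- suppressWarnings(as.numeric(ch))
  r[ch == "X"] <- 100; r[ch == "Y"] <- 101
  r[is.na(r)] <- 102 + as.integer(factor(ch[is.na(r)]))
  r
}

#' Cluster an inferred-CNV profile into a dendrogram
#'
#' Ward linkage on Euclidean distances between the per-sample smoothed
#' score vectors.
#'
#' @param profile an [infer_cnv_profile()] result (or a plain
#'   genes x samples score matrix).
#' @param linkage linkage method, `"ward.D"` by default.
#' @return a [stats::dendrogram].
#' @export
build_icnv_tree <- function(profile, linkage = "ward.D") {
  scores <- if (inherits(profile, "icnv_profile")) profile$scores else
    as.matrix(profile)
  d <- as.matrix(dist(t(scores)))
  hclust_tree(dist_matrix(d), linkage)
}

#' Genomic-CNV dendrogram from per-sample segment tables
#'
#' Rasterizes each sample's copy-number segments onto fixed-width genomic
#' bins ([bin_segments()]), then clusters samples by Euclidean distance
#' between CN vectors with Ward linkage.  Bins uncovered in a sample are
#' missing and excluded pairwise: the distance between two samples is the
#' root-sum-of-squares over bins covered in both (a pair sharing no bin is
#' an error).
#'
#' @param segments named list of per-sample segment data.frames
#'   (`chrom`, `start`, `end`, `total_cn`; 1-based inclusive coordinates).
#' @param bin_bp bin width in bp.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param linkage linkage method.
#' @return a [stats::dendrogram].
#' @export
gcnv_tree <- function(segments, bin_bp, chrom_lengths, linkage = "ward.D") {
  m <- bin_segment_matrix(segments, bin_bp, chrom_lengths)
  ns <- ncol(m)
  labs <- colnames(m)
  d <- matrix(0, ns, ns, dimnames = list(labs, labs))
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (j <= i) next
    ok <- !is.na(m[, i]) & !is.na(m[, j])
    if (!any(ok)) stop("samples '", labs[i], "' and '", labs[j],
                       "' share no covered bin")
    d[i, j] <- d[j, i] <- sqrt(sum((m[ok, i] - m[ok, j])^2))
  }
  hclust_tree(dist_matrix(d), linkage)
}
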