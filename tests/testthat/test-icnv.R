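ann_for <- function(g) clonotangle:::gene_map(g)$annotation

test_that("pseudobulk sums spot counts within sections", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  one_per <- pseudobulk(m, c(s1 = "a", s2 = "b", s3 = "c"))
  expect_equal(unname(one_per), unname(m))

  m2 <- matrix(c(1, 2, 3), 1, 3,
               dimnames = list("g1", c("s1", "s2", "s3")))
  expect_equal(unname(pseudobulk(m2, rep("sec1", 3))[1, 1]), 6)
  expect_error(pseudobulk(m, c(s1 = "a", s2 = "b")), "without a section")
})

test_that("uniform diploid noise-free input yields an all-zero profile", {
  g <- 200
  ann <- ann_for(g)
  base <- rlnorm(g, 2, 1)
  counts <- round(outer(base, rep(1, 6)))
  rownames(counts) <- ann$gene; colnames(counts) <- paste0("s", 1:6)
  p <- infer_cnv_profile(counts, ann, window = 11)
  expect_true(all(p$scores == 0))
  expect_true(all(abs(apply(p$scores, 2, median)) < 1e-9))
})

test_that("a clean single-arm gain produces a separated positive score block", {
  set.seed(21)
  g <- 2000
  ann <- ann_for(g)
  base <- rlnorm(g, 3, 0.8)
  cn <- matrix(2, g, 6)
  gain_genes <- which(ann$chrom == "chr1")[10:59]   # 50-gene event
  cn[gain_genes, 1:3] <- 3                           # gain cohort
  counts <- round(base * cn / 2)
  rownames(counts) <- ann$gene; colnames(counts) <- paste0("s", 1:6)
  p <- infer_cnv_profile(counts, ann, window = 21, denoise_sd = 0)
  s_res <- sd(p$scores)
  inside <- colMeans(p$scores[gain_genes, 1:3])
  outside <- colMeans(p$scores[-gain_genes, 1:3])
  expect_true(all(inside > outside))
  expect_gt(min(inside) - max(outside), 5 * s_res)
})

test_that("the mean-count cutoff removes low genes and empty results error", {
  ann <- ann_for(60)
  counts <- matrix(1, 60, 4, dimnames = list(ann$gene, paste0("s", 1:4)))
  counts[1, ] <- 0.05
  p <- infer_cnv_profile(counts, ann, cutoff = 0.1, window = 5)
  expect_false(ann$gene[1] %in% rownames(p$scores))
  expect_error(infer_cnv_profile(counts * 0 + 0.01, ann, cutoff = 0.1,
                                 window = 5), "cutoff")
  expect_error(infer_cnv_profile(counts, ann, window = 4), "odd")
})

test_that("the smoothing stage is linear (superposition)", {
  set.seed(5)
  x <- rnorm(100); y <- rnorm(100)
  for (w in c(5, 21)) {
    expect_equal(clonotangle:::running_mean_trunc(x + y, w),
                 clonotangle:::running_mean_trunc(x, w) +
                   clonotangle:::running_mean_trunc(y, w))
  }
})

test_that("profiles are invariant to gene relabeling that preserves genomic order", {
  b <- sim_preset("sidr_like", seed = 3)
  counts <- b$rna$counts
  ann <- b$annotation
  p1 <- infer_cnv_profile(counts, ann, window = 11)
  ann2 <- ann; ann2$gene <- paste0("X", ann$gene)
  counts2 <- counts; rownames(counts2) <- paste0("X", rownames(counts))
  p2 <- infer_cnv_profile(counts2, ann2, window = 11)
  expect_equal(unname(p1$scores), unname(p2$scores))
})

test_that("mean profile score is non-decreasing in true copy number", {
  set.seed(31)
  g <- 2000
  ann <- ann_for(g)
  base <- rlnorm(g, 3, 0.8)
  region <- which(ann$chrom == "chr2")[5:54]
  cohorts <- c(1, 2, 3, 4)
  cn <- matrix(2, g, 8)
  for (i in seq_along(cohorts)) cn[region, c(2 * i - 1, 2 * i)] <- cohorts[i]
  counts <- round(base * cn / 2)
  rownames(counts) <- ann$gene; colnames(counts) <- paste0("s", 1:8)
  p <- infer_cnv_profile(counts, ann, window = 21, denoise_sd = 0)
  mean_score <- vapply(seq_along(cohorts), function(i)
    mean(p$scores[region, c(2 * i - 1, 2 * i)]), numeric(1))
  expect_true(all(diff(mean_score) > 0))
})

test_that("iCNV clustering recovers populations and merges duplicates at height 0", {
  b <- sim_preset("sidr_like", seed = 1)
  p <- infer_cnv_profile(b$rna$counts, b$annotation)
  t <- build_icnv_tree(p)
  part <- stats::cutree(stats::as.hclust(t), k = 3)
  expect_equal(mclust::adjustedRandIndex(part[names(b$truth)], b$truth), 1)

  dup <- cbind(p$scores, zz_dup = p$scores[, 5])
  td <- build_icnv_tree(dup)
  expect_equal(cophenetic_dist(td)[colnames(p$scores)[5], "zz_dup"], 0)
})

test_that("spatial sections split into tumour and normal clades", {
  for (seed in 1:5) {
    b <- sim_preset("st_12section_like", seed = seed)
    counts <- pseudobulk(b$rna$counts, b$section_of)
    t <- build_icnv_tree(infer_cnv_profile(counts, b$annotation))
    part <- stats::cutree(stats::as.hclust(t), k = 2)
    expect_equal(mclust::adjustedRandIndex(part[names(b$truth)], b$truth), 1)
  }
})

test_that("gCNV binning distance follows direct arithmetic and recovers populations", {
  # two units differing by a 10-bin amplification: squared distance 10*delta^2
  bin <- 1000
  len <- c(chr1 = 30 * bin)
  segA <- data.frame(chrom = "chr1", start = 1, end = 30 * bin, total_cn = 2)
  segB <- data.frame(chrom = "chr1",
                     start = c(1, 5 * bin + 1, 15 * bin + 1),
                     end = c(5 * bin, 15 * bin, 30 * bin),
                     total_cn = c(2, 4, 2))
  t <- gcnv_tree(list(a = segA, b = segB), bin_bp = bin, chrom_lengths = len)
  expect_equal(attr(t, "height"), sqrt(10 * 2^2))   # ward 2-leaf: height = d

  ident <- gcnv_tree(list(a = segA, b = segA, c = segA), bin_bp = bin,
                     chrom_lengths = len)
  expect_true(all(cophenetic_dist(ident) == 0))

  b <- sim_preset("sidr_like", seed = 2)
  tg <- gcnv_tree(b$dna$segments, bin_bp = 10000,
                  chrom_lengths = b$chrom_lengths)
  part <- stats::cutree(stats::as.hclust(tg), k = 3)
  expect_equal(mclust::adjustedRandIndex(part[names(b$truth)], b$truth), 1)
})
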