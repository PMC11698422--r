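test_that("segments rasterize by the bin-midpoint rule", {
  len <- c(chr1 = 3600)
  one <- data.frame(chrom = "chr1", start = 1, end = 3600, total_cn = 3)
  expect_equal(as.vector(bin_segments(one, 1200, len)), c(3, 3, 3))

  two <- data.frame(chrom = "chr1", start = c(1, 1801), end = c(1800, 3600),
                    total_cn = c(3, 2))
  expect_equal(as.vector(bin_segments(two, 1200, len)), c(3, 2, 2))

  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), total_cn = numeric(0))
  expect_true(all(is.na(bin_segments(empty, 1200, len))))

  ovl <- data.frame(chrom = "chr1", start = c(1, 1500), end = c(1800, 3600),
                    total_cn = c(3, 2))
  expect_error(bin_segments(ovl, 1200, len), "overlapping")
  out <- data.frame(chrom = "chr1", start = 1, end = 4000, total_cn = 2)
  expect_error(bin_segments(out, 1200, len), "bounds")
})

test_that("genome bin count is the ceil-sum over chromosomes", {
  lens <- c(chrA = 5000, chrB = 1199, chrC = 2400)
  seg <- data.frame(chrom = "chrA", start = 1, end = 5000, total_cn = 2)
  v <- bin_segments(seg, 1200, lens)
  expect_length(v, ceiling(5000 / 1200) + ceiling(1199 / 1200) +
                  ceiling(2400 / 1200))
  bins <- attr(v, "bins")
  expect_equal(sum(bins$chrom == "chrB"), 1)
  expect_equal(bins$end[bins$chrom == "chrB"], 1199)
})

test_that("thresholded calls use inclusive boundaries around diploid", {
  cn <- c(1.0, 1.5, 2.0, 2.5, 3.0, NA)
  expect_equal(as.vector(call_bins(cn)), c(-1L, -1L, 0L, 1L, 1L, NA))
  expect_error(call_bins(cn, del_cn = 3, amp_cn = 2), "below")
})

test_that("discordant filtering drops incomplete and shared bins", {
  calls <- rbind(c(1, 1), c(0, 0), c(-1, -1), c(1, 0))
  colnames(calls) <- c("a", "b")
  m <- discordant_matrix(calls)
  expect_equal(nrow(m$calls), 1)
  expect_equal(m$n_dropped_shared, 3)

  withNA <- rbind(c(1, NA), c(1, 0))
  colnames(withNA) <- c("a", "b")
  m2 <- discordant_matrix(withNA)
  expect_equal(m2$n_dropped_missing, 1)

  allsame <- matrix(1, 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(m3 <- discordant_matrix(allsame), "no discordant")
  expect_equal(nrow(m3$calls), 0)
  expect_error(bootstrap_tree(m3), "at least 2")
})

test_that("the filtered matrix is invariant to sample order", {
  bund <- make_discordant_bundle()
  m <- bin_segment_matrix(bund$seg_list, bund$bin_bp, bund$chrom_lengths)
  calls <- call_bins(m)
  d1 <- discordant_matrix(calls)
  perm <- sample(ncol(calls))
  calls2 <- calls[, perm]
  attr(calls2, "bins") <- attr(calls, "bins")
  d2 <- discordant_matrix(calls2)
  expect_equal(d2$calls[, colnames(d1$calls)], d1$calls)
})

test_that("the engineered 12-sample bundle leaves exactly 28 discordant bins", {
  bund <- make_discordant_bundle()
  m <- bin_segment_matrix(bund$seg_list, bund$bin_bp, bund$chrom_lengths)
  dm <- discordant_matrix(call_bins(m), bin_bp = bund$bin_bp)
  expect_equal(nrow(dm$calls), 28)
  expect_equal(ncol(dm$calls), 12)
})

test_that("bootstrap support is 1.0 for a unanimous group split and runs are seed-stable", {
  bund <- make_discordant_bundle()
  m <- bin_segment_matrix(bund$seg_list, bund$bin_bp, bund$chrom_lengths)
  dm <- discordant_matrix(call_bins(m), bin_bp = bund$bin_bp)
  t <- bootstrap_tree(dm, n_boot = 200, seed = 42)
  for (side in 1:2) {
    kid <- t[[side]]
    expect_setequal(clonotangle:::leaf_labels_dend(kid),
                    bund$samples[bund$groups ==
                                   (if ("G1_s1" %in%
                                        clonotangle:::leaf_labels_dend(kid))
                                      "G1" else "G2")])
    expect_equal(attr(kid, "support"), 1.0)
  }
  t2 <- bootstrap_tree(dm, n_boot = 200, seed = 42)
  expect_equal(attr(t, "support_table"), attr(t2, "support_table"))

  base_only <- bootstrap_tree(dm, n_boot = 0)
  expect_null(attr(base_only, "support_table"))
  expect_null(attr(base_only[[1]], "support"))
})

test_that("bootstrap support rises with inter-group signal", {
  support_at <- function(n_disc, seed) {
    bund <- make_discordant_bundle(n_disc = n_disc)
    m <- bin_segment_matrix(bund$seg_list, bund$bin_bp, bund$chrom_lengths)
    # soften the signal: flip a fixed fraction of calls to random noise
    calls <- call_bins(m)
    dm <- discordant_matrix(calls, bin_bp = bund$bin_bp)
    cc <- dm$calls
    set.seed(seed)
    flip <- cbind(sample(nrow(cc), 20, replace = TRUE),
                  sample(ncol(cc), 20, replace = TRUE))
    cc[flip] <- sample(c(-1, 0, 1), 20, replace = TRUE)
    t <- bootstrap_tree(cc, n_boot = 100, seed = seed)
    g1 <- sort(bund$samples[bund$groups == "G1"])
    tab <- attr(t, "support_table")
    hit <- tab$support[tab$leaves == paste(g1, collapse = ",")]
    if (length(hit)) hit else 0
  }
  # more discordant bins -> cleaner split -> higher support
  s_lo <- mean(vapply(1:3, function(s) support_at(6, s), numeric(1)))
  s_hi <- mean(vapply(1:3, function(s) support_at(28, s), numeric(1)))
  expect_gte(s_hi, s_lo)
  expect_gt(s_hi, 0.8)
})

test_that("supported trees serialize to Newick with node labels", {
  bund <- make_discordant_bundle()
  m <- bin_segment_matrix(bund$seg_list, bund$bin_bp, bund$chrom_lengths)
  dm <- discordant_matrix(call_bins(m), bin_bp = bund$bin_bp)
  t <- bootstrap_tree(dm, n_boot = 50, seed = 1)
  nwk <- write_newick(t)
  t2 <- read_newick(nwk)
  expect_equal(attr(t2[[1]], "support"), attr(t[[1]], "support"))
})
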