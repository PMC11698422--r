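test_that("zero event rates give identical diploid clones; repeat calls are deterministic", {
  ct <- simulate_clone_tree(m = 2, g = 60, s = 20,
                            events_per_branch = list(cnv = 0, snv = 0),
                            seed = 5)
  expect_true(all(ct$clone_cn == 2))
  expect_true(all(ct$clone_geno == 0))

  a <- simulate_clone_tree(m = 4, seed = 11)
  b <- simulate_clone_tree(m = 4, seed = 11)
  expect_identical(a$clone_cn, b$clone_cn)
  expect_identical(a$clone_geno, b$clone_geno)
  expect_identical(a$topology_newick, b$topology_newick)
})

test_that("branch events accumulate root-to-leaf onto clone profiles", {
  # find a clone tree where some branch carries a single gain and check the
  # affected span directly against the event log
  ct <- simulate_clone_tree(m = 3, g = 100, s = 30,
                            events_per_branch = list(cnv = 1, snv = 2),
                            span_genes = c(10, 11), seed = 2)
  # every clone profile must equal the sum of deltas along its root path
  ev <- ct$events
  expected <- matrix(2L, ct$g, ct$m)
  path_edges <- function(cl) {
    out <- integer(0); node <- cl
    repeat {
      e <- which(ev$child == node)
      if (!length(e)) break
      out <- c(out, e); node <- ev$parent[e]
    }
    out
  }
  for (cl in seq_len(ct$m)) {
    cn <- rep(2L, ct$g)
    for (e in rev(path_edges(cl))) {
      cnv <- ev$cnv[[e]]
      if (!is.null(cnv))
        for (r in seq_len(nrow(cnv))) {
          idx <- cnv$start[r]:cnv$end[r]
          cn[idx] <- cn[idx] + cnv$delta[r]
        }
      cn <- pmax(cn, 0L)
    }
    expect_equal(unname(ct$clone_cn[, cl]), cn)
  }
})

test_that("noise-free single-cell DNA reproduces clone genotypes exactly; purity 0 bulk is diploid", {
  ct <- simulate_clone_tree(m = 3, g = 100, s = 40, seed = 4)
  des <- sample_design("single_cell", assignment = c(1, 1, 2, 3),
                       unit_names = paste0("c", 1:4))
  obs <- observe_dna(ct, des)
  expect_equal(unname(obs$geno), unname(ct$clone_geno[, c(1, 1, 2, 3)]))
  expect_equal(unname(obs$cn), unname(ct$clone_cn[, c(1, 1, 2, 3)]))

  w <- matrix(c(0.5, 0.5, 0, 0.2, 0.3, 0.5), 2, byrow = TRUE)
  desb <- sample_design("bulk", assignment = w, purity = 0)
  obsb <- observe_dna(ct, desb)
  expect_true(all(obsb$cn == 2))
  expect_true(all(obsb$geno == 0))
  expect_true(all(vapply(obsb$segments, function(s) all(s$total_cn == 2),
                         logical(1))))
})

test_that("observed dropout fraction concentrates at the configured rate", {
  ct <- simulate_clone_tree(m = 2, g = 60, s = 1000,
                            events_per_branch = list(cnv = 0, snv = 500),
                            seed = 3)
  des <- sample_design("single_cell", assignment = c(1, 2))
  het_before <- sum(ct$clone_geno == 1)
  expect_gt(het_before, 500)
  set.seed(3)
  obs <- observe_dna(ct, des, noise_config(ado_rate = 0.2))
  dropped <- sum(ct$clone_geno == 1 & obs$geno != 1)
  p_hat <- dropped / het_before
  se3 <- 3 * sqrt(0.2 * 0.8 / het_before)
  expect_lt(abs(p_hat - 0.2), se3)
})

test_that("RNA counts track base expression and copy-number dosage", {
  ct <- simulate_clone_tree(m = 2, g = 60, s = 20,
                            events_per_branch = list(cnv = 0, snv = 0),
                            seed = 6)
  des <- sample_design("single_cell", assignment = rep(1, 200))
  base <- rep(50, ct$g)
  set.seed(9)
  rna <- observe_rna(ct, des, noise_config(nb_dispersion = 0.05),
                     base_expr = base)
  gm <- rowMeans(rna$counts)
  se <- sqrt((50 + 0.05 * 50^2) / 200)
  expect_true(all(abs(gm - 50) < 3 * se + 0.5))

  # CN 4 vs CN 2 cohorts: mean ratio ~ 2
  cn4 <- ct; cn4$clone_cn[, 1] <- 4L
  set.seed(10)
  rna4 <- observe_rna(cn4, des, noise_config(nb_dispersion = 0.05),
                      base_expr = base)
  ratio <- mean(rna4$counts) / mean(rna$counts)
  expect_lt(abs(ratio - 2), 0.1)

  z <- observe_rna(ct, des, base_expr = rep(0, ct$g))
  expect_true(all(z$counts == 0))
})

test_that("log mean expression regresses on log relative dosage with slope near 1", {
  ct <- simulate_clone_tree(m = 2, g = 440, s = 30,
                            events_per_branch = list(cnv = 8, snv = 5),
                            seed = 12)
  des <- sample_design("single_cell", assignment = rep(2, 200))
  set.seed(12)
  base <- rlnorm(ct$g, 2.5, 1)
  set.seed(13)
  rna <- observe_rna(ct, des, noise_config(nb_dispersion = 0.2),
                     base_expr = base)
  cn <- ct$clone_cn[, 2]
  ok <- cn > 0 & rowMeans(rna$counts) > 0 & base > 1
  fit <- stats::lm(log(rowMeans(rna$counts)[ok] / base[ok]) ~ log(cn[ok] / 2))
  expect_gt(coef(fit)[2], 0.8)
  expect_lt(coef(fit)[2], 1.2)
})

test_that("presets have the documented unit counts and record ground truth", {
  b <- sim_preset("sidr_like", seed = 7)
  expect_equal(b$design$n_units, 30)
  expect_equal(unname(table(b$truth)[c("P1", "P2", "P3")]), c(10L, 7L, 13L),
               ignore_attr = TRUE)

  b2 <- sim_preset("bulk_a21_like", seed = 7)
  expect_equal(b2$design$n_units, 7)
  expect_equal(ncol(b2$rna$counts), 7)

  b3 <- sim_preset("st_12section_like", seed = 7)
  expect_equal(b3$design$n_units, 12)
  expect_equal(ncol(pseudobulk(b3$rna$counts, b3$section_of)), 12)
  expect_equal(sum(b3$design$purity > 0.5), 4)

  # determinism across repeat calls
  expect_identical(sim_preset("sidr_like", seed = 7)$rna$counts,
                   b$rna$counts)
})

test_that("bundles round-trip through the plain-text writers", {
  b <- sim_preset("sidr_like", seed = 1)
  dir <- tempfile()
  write_bundle(b, dir)
  counts <- as.matrix(read.delim(file.path(dir, "counts.tsv"), row.names = 1,
                                 check.names = FALSE))
  expect_equal(counts, b$rna$counts, ignore_attr = TRUE)
  expect_length(validate_inputs(list(
    counts = file.path(dir, "counts.tsv"),
    annotation = file.path(dir, "genes.tsv"),
    segments = file.path(dir, "segments"),
    chrom_lengths = file.path(dir, "chrom_lengths.tsv"),
    newick = file.path(dir, "clone_tree.nwk"))), 0)
})
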