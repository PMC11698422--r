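#' Derive a reproducible per-module seed from a master seed
#'
#' Stable integer hashing of the module name mixed with the master seed,
#' kept below 2^31, so that adding one module's draws never perturbs
#' another's.
#'
#' @param master master integer seed.
#' @param stream character stream name.
#' @return integer seed.
#' @export
derive_seed <- function(master, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(master) * 69069 + h * 30011) %% 2147483629)
}

#' Simulated data bundles emulating the three study regimes
#'
#' One call generates the ground truth and both molecular channels of a
#' full experiment:
#'
#' * `"sidr_like"` — 30 single cells from 3 strongly distinct
#'   populations of 10, 7 and 13 cells, each cell with paired DNA
#'   (genotypes + copy-number segments) and RNA (counts + variant reads).
#' * `"bulk_a21_like"` — 7 multi-region bulk tumour samples from a
#'   4-clone tree, each dominated by one clone at 70% purity.
#' * `"st_12section_like"` — 12 spatial sections of 20 spots each, 4
#'   sections carrying tumour (60% tumour fraction) and 8 near-normal
#'   (2%), with section-level DNA and spot-level RNA (pseudo-bulk the
#'   spots with [pseudobulk()] and `bundle$section_of`).
#'
#' The default noise configuration is noise-free (deterministic); pass a
#' [noise_config()] to add allelic dropout, overdispersion etc.  All
#' randomness derives from `seed` through per-stream seeds
#' ([derive_seed()]), so bundles are fully reproducible.
#'
#' @param name preset name.
#' @param seed master integer seed.
#' @param noise a [noise_config()].
#' @return list of class `"sim_bundle"`: `clone_tree`, `design`, `noise`,
#'   `dna` (geno/cn/segments), `rna` (counts/alt/total/base_expr),
#'   `annotation`, `chrom_lengths`, `truth` (unit to population label),
#'   `k` (true cluster count), `section_of` (spatial only) and
#'   `manifest` (all parameters).
#' @export
sim_preset <- function(name = c("sidr_like", "bulk_a21_like",
                                "st_12section_like"),
                       seed = 1, noise = noise_config()) {
  name <- match.arg(name)
  stopifnot(inherits(noise, "noise_config"))
  if (name == "sidr_like") {
    ct <- simulate_clone_tree(m = 3, g = 440, s = 120,
                              events_per_branch = list(cnv = 5, snv = 25),
                              seed = derive_seed(seed, "clone_tree"))
    sizes <- c(P1 = 10, P2 = 7, P3 = 13)
    cells <- unlist(lapply(seq_along(sizes), function(k)
      sprintf("%s_c%02d", names(sizes)[k], seq_len(sizes[k]))))
    design <- sample_design("single_cell",
                            assignment = rep(seq_along(sizes), sizes),
                            unit_names = cells)
    truth <- setNames(rep(names(sizes), sizes), cells)
    k <- 3L
  } else if (name == "bulk_a21_like") {
    ct <- simulate_clone_tree(m = 4, g = 440, s = 120,
                              events_per_branch = list(cnv = 5, snv = 25),
                              seed = derive_seed(seed, "clone_tree"))
    n <- 7
    dom <- c(1, 1, 2, 2, 3, 4, 4)      # dominant clone per region
    w <- matrix(0.2 / 3, n, 4)
    for (u in seq_len(n)) w[u, dom[u]] <- 0.8
    design <- sample_design("bulk", assignment = w, purity = 0.7,
                            unit_names = sprintf("R%02d", seq_len(n)))
    truth <- setNames(paste0("clone", dom), design$unit_names)
    k <- 4L
  } else {
    ct <- simulate_clone_tree(m = 3, g = 440, s = 120,
                              events_per_branch = list(cnv = 5, snv = 25),
                              seed = derive_seed(seed, "clone_tree"))
    n_sec <- 12; spots_per <- 20
    tumour_sec <- c(1, 2, 3, 4)
    sec_names <- sprintf("sec%02d", seq_len(n_sec))
    set.seed(derive_seed(seed, "spatial_design"))
    # tumour sections share one clonal composition (perturbed slightly),
    # as adjacent regions of a single tumour do; normal sections carry a
    # negligible tumour fraction so their mixture barely matters
    base_mix <- c(3, 2, 1)
    w_sec <- matrix(0, n_sec, 3)
    for (u in seq_len(n_sec)) {
      v <- base_mix + runif(3, 0, 0.5)
      w_sec[u, ] <- v / sum(v)
    }
    pur <- ifelse(seq_len(n_sec) %in% tumour_sec, 0.6, 0.02)
    design <- sample_design("spatial", assignment = w_sec, purity = pur,
                            unit_names = sec_names)
    spot_names <- as.vector(vapply(sec_names, function(s)
      sprintf("%s_s%02d", s, seq_len(spots_per)), character(spots_per)))
    spot_design <- sample_design("spatial",
                                 assignment = w_sec[rep(seq_len(n_sec),
                                                        each = spots_per), ],
                                 purity = rep(pur, each = spots_per),
                                 unit_names = spot_names)
    truth <- setNames(ifelse(seq_len(n_sec) %in% tumour_sec,
                             "tumour", "normal"), sec_names)
    k <- 2L
  }
  set.seed(derive_seed(seed, "dna"))
  dna <- observe_dna(ct, design, noise)
  set.seed(derive_seed(seed, "base_expr"))
  base_expr <- rlnorm(ct$g, meanlog = 2.5, sdlog = 1)
  set.seed(derive_seed(seed, "rna"))
  rna_design <- if (name == "st_12section_like") spot_design else design
  rna <- observe_rna(ct, rna_design, noise, base_expr = base_expr)
  bundle <- list(
    name = name, seed = seed, clone_tree = ct, design = design,
    noise = noise, dna = dna, rna = rna,
    annotation = ct$annotation, chrom_lengths = ct$chrom_lengths,
    truth = truth, k = k,
    manifest = list(preset = name, seed = seed, noise = unclass(noise),
                    m = ct$m, g = ct$g, s = ct$s,
                    clone_params = ct$params))
  if (name == "st_12section_like")
    bundle$section_of <- setNames(rep(sec_names, each = spots_per),
                                  spot_names)
  class(bundle) <- "sim_bundle"
  bundle
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("Simulated bundle '", x$name, "' (seed ", x$seed, "): ",
      x$design$n_units, " units, ", x$clone_tree$m, " clones\n", sep = "")
  invisible(x)
}

#' Write a simulated bundle to plain-text files
#'
#' Emits the standard interchange files: counts TSV, gene annotation TSV,
#' genotype TSV, per-unit segment TSVs, the ground-truth clone topology
#' in Newick, and a JSON manifest of all parameters.
#'
#' @param bundle a [sim_preset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(x, f, rn) {
    df <- data.frame(id = rownames(x), x, check.names = FALSE)
    names(df)[1] <- rn
    write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wtsv(bundle$rna$counts, "counts.tsv", "gene")
  wtsv(bundle$dna$geno, "genotypes.tsv", "site")
  wtsv(bundle$rna$alt, "alt_reads.tsv", "site")
  wtsv(bundle$rna$total, "total_reads.tsv", "site")
  write.table(bundle$annotation, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  seg_dir <- file.path(dir, "segments")
  dir.create(seg_dir, showWarnings = FALSE)
  for (u in names(bundle$dna$segments))
    write.table(bundle$dna$segments[[u]],
                file.path(seg_dir, paste0(u, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  write.table(data.frame(chrom = names(bundle$chrom_lengths),
                         length = as.numeric(bundle$chrom_lengths)),
              file.path(dir, "chrom_lengths.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(bundle$clone_tree$topology_newick,
             file.path(dir, "clone_tree.nwk"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
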