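#' Noise configuration for simulated observations
#'
#' All-zero defaults give fully deterministic, noise-free observations
#' (counts and read totals are rounded expectations), which is the
#' backbone configuration for exact ground-truth recovery checks.
#' `nb_dispersion = 0` means "no overdispersion draw" rather than a
#' degenerate negative binomial.
#'
#' @param ado_rate allelic-dropout probability for heterozygous sites in
#'   single-cell DNA genotypes, in `[0, 1)`.
#' @param fp_rate spurious-variant probability per reference site, `[0, 1)`.
#' @param nb_dispersion negative-binomial dispersion of RNA counts
#'   (variance = mu + dispersion * mu^2); 0 = deterministic counts.
#' @param libsize_log_sd log-normal SD of per-unit library size factors.
#' @param depth_mean mean per-site read depth for RNA variant reads.
#' @param cn_jitter_sd SD of the integer-rounded Gaussian jitter added to
#'   single-cell DNA copy-number profiles.
#' @param geno_threshold minimum mixture expected dosage for a variant to
#'   be called present in bulk/spatial DNA.
#' @return list of class `"noise_config"`.
#' @export
noise_config <- function(ado_rate = 0, fp_rate = 0, nb_dispersion = 0,
                         libsize_log_sd = 0, depth_mean = 30,
                         cn_jitter_sd = 0, geno_threshold = 0.1) {
  stopifnot(ado_rate >= 0, ado_rate < 1, fp_rate >= 0, fp_rate < 1,
            nb_dispersion >= 0, libsize_log_sd >= 0, depth_mean > 0,
            cn_jitter_sd >= 0)
  structure(list(ado_rate = ado_rate, fp_rate = fp_rate,
                 nb_dispersion = nb_dispersion,
                 libsize_log_sd = libsize_log_sd, depth_mean = depth_mean,
                 cn_jitter_sd = cn_jitter_sd,
                 geno_threshold = geno_threshold),
            class = "noise_config")
}

#' Sampling design linking observation units to clones
#'
#' @param mode `"single_cell"`, `"bulk"` or `"spatial"`.
#' @param assignment single-cell mode: integer clone index per unit;
#'   bulk/spatial: units x clones matrix of clone fractions, rows summing
#'   to 1.
#' @param purity tumour fraction per unit in `[0, 1]` (recycled; single
#'   cells are pure tumour by default).
#' @param unit_names labels for the units (cells/samples/sections).
#' @return list of class `"sample_design"`.
#' @export
sample_design <- function(mode = c("single_cell", "bulk", "spatial"),
                          assignment, purity = 1, unit_names = NULL) {
  mode <- match.arg(mode)
  if (mode == "single_cell") {
    n <- length(assignment)
  } else {
    assignment <- as.matrix(assignment)
    n <- nrow(assignment)
    if (max(abs(rowSums(assignment) - 1)) > 1e-8)
      stop("clone fraction rows must sum to 1")
    if (any(assignment < 0)) stop("negative clone fractions")
  }
  purity <- rep_len(purity, n)
  if (any(purity < 0 | purity > 1)) stop("purity must be in [0, 1]")
  if (is.null(unit_names)) unit_names <- sprintf("U%02d", seq_len(n))
  if (anyDuplicated(unit_names)) stop("duplicate unit names")
  structure(list(mode = mode, n_units = n, assignment = assignment,
                 purity = purity, unit_names = unit_names),
            class = "sample_design")
}

# deterministic gene -> genome mapping: 22 autosomes, genes split evenly
# in contiguous blocks, uniform 10-kb gene spacing
gene_map <- function(g, gene_bp = 10000, n_chrom = 22) {
  per <- diff(floor(seq(0, g, length.out = n_chrom + 1)))
  chrom <- rep(paste0("chr", seq_len(n_chrom)), per)
  idx <- unlist(lapply(per, seq_len))
  ann <- data.frame(gene = sprintf("g%04d", seq_len(g)), chrom = chrom,
                    start = (idx - 1) * gene_bp + 1, end = idx * gene_bp)
  lens <- tapply(ann$end, ann$chrom, max)
  list(annotation = ann,
       chrom_lengths = setNames(as.numeric(lens), names(lens)))
}

#' Simulate a ground-truth clone tree with CNV and SNV events
#'
#' Grows a random rooted binary topology over `m` clones (iterative leaf
#' splitting), then places events on every branch: CNV events are
#' contiguous gene spans gaining or losing one copy (span length uniform
#' within `span_genes`), SNV events mark previously unmutated sites
#' heterozygous (infinite-sites; sites are recycled only if exhausted).
#' States accumulate root-to-leaf from a diploid, variant-free root; copy
#' numbers are floored at 0 (clipping is reported via a message).
#'
#' @param m number of clones (`>= 2`).
#' @param g number of genes (`>= 50`).
#' @param s number of variant sites (`>= 20`).
#' @param events_per_branch list with Poisson rates `cnv` and `snv` per
#'   branch.
#' @param span_genes CNV span bounds in genes.
#' @param seed RNG seed.
#' @param gene_bp uniform gene spacing in bp for the genome mapping.
#' @return object of class `"clone_tree"`: list with `m`, `g`, `s`,
#'   `clone_cn` (genes x clones), `clone_geno` (sites x clones),
#'   `events` (per-branch log), `annotation`, `chrom_lengths`,
#'   `site_gene` (host gene per site) and `topology_newick`.
#' @export
simulate_clone_tree <- function(m, g = 440, s = 120,
                                events_per_branch = list(cnv = 5, snv = 25),
                                span_genes = c(15, 45), seed = 1,
                                gene_bp = 10000) {
  stopifnot(m >= 2, g >= 50, s >= 20, span_genes[1] >= 1,
            span_genes[2] >= span_genes[1])
  set.seed(seed)
  gm <- gene_map(g, gene_bp = gene_bp)
  # topology by iterative leaf splitting; edges as (parent, child) ids
  # node ids: 1..m clones (leaves), m+1.. internal; root = m+1
  parent <- integer(0); child <- integer(0)
  next_int <- m + 1L
  root <- next_int; next_int <- next_int + 1L
  parent <- c(root, root); child <- c(1L, 2L)
  leaves <- c(1L, 2L)
  for (k in seq_len(m - 2)) {
    cl <- k + 2L
    split_leaf <- if (length(leaves) == 1) leaves else sample(leaves, 1)
    nid <- next_int; next_int <- next_int + 1L
    parent[child == split_leaf] <- parent[child == split_leaf]
    # replace edge (p -> split_leaf) by (p -> nid), (nid -> split_leaf),
    # (nid -> cl)
    child[child == split_leaf] <- nid
    parent <- c(parent, nid, nid); child <- c(child, split_leaf, cl)
    leaves <- c(leaves, cl)
  }
  n_edges <- length(parent)
  ev_cnv <- vector("list", n_edges); ev_snv <- vector("list", n_edges)
  free_sites <- sample.int(s)
  clipped <- 0L
  for (e in seq_len(n_edges)) {
    nc <- rpois(1, events_per_branch$cnv)
    if (nc > 0) {
      st <- sample.int(g, nc, replace = TRUE)
      len <- sample(seq(span_genes[1], span_genes[2]), nc, replace = TRUE)
      ev_cnv[[e]] <- data.frame(start = st,
                                end = pmin(st + len - 1L, g),
                                delta = sample(c(-1L, 1L), nc, replace = TRUE))
    }
    ns <- rpois(1, events_per_branch$snv)
    if (ns > 0) {
      take <- head(free_sites, ns)
      free_sites <- free_sites[-seq_along(take)]
      if (length(take) < ns)
        take <- c(take, sample.int(s, ns - length(take), replace = TRUE))
      ev_snv[[e]] <- take
    }
  }
  clone_cn <- matrix(NA_integer_, g, m,
                     dimnames = list(gm$annotation$gene,
                                     paste0("clone", seq_len(m))))
  clone_geno <- matrix(NA_integer_, s, m,
                       dimnames = list(sprintf("site%03d", seq_len(s)),
                                       colnames(clone_cn)))
  acc <- function(node, cn, geno) {
    if (node <= m) { clone_cn[, node] <<- cn; clone_geno[, node] <<- geno; return(invisible()) }
    for (e in which(parent == node)) {
      cn2 <- cn; geno2 <- geno
      if (!is.null(ev_cnv[[e]]))
        for (r in seq_len(nrow(ev_cnv[[e]]))) {
          idx <- ev_cnv[[e]]$start[r]:ev_cnv[[e]]$end[r]
          cn2[idx] <- cn2[idx] + ev_cnv[[e]]$delta[r]
        }
      neg <- cn2 < 0
      if (any(neg)) { clipped <<- clipped + sum(neg); cn2[neg] <- 0L }
      if (!is.null(ev_snv[[e]]))
        geno2[ev_snv[[e]]] <- pmax(geno2[ev_snv[[e]]], 1L)
      acc(child[e], cn2, geno2)
    }
  }
  acc(root, rep(2L, g), rep(0L, s))
  if (clipped > 0)
    message("copy number clipped at 0 for ", clipped, " gene-branch states")
  nwk <- local({
    rec <- function(node) {
      if (node <= m) return(paste0("clone", node, ":1"))
      kids <- child[parent == node]
      paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), "):1")
    }
    paste0(sub(":1$", "", rec(root)), ";")
  })
  structure(list(
    m = m, g = g, s = s, clone_cn = clone_cn, clone_geno = clone_geno,
    events = list(parent = parent, child = child, cnv = ev_cnv, snv = ev_snv),
    annotation = gm$annotation, chrom_lengths = gm$chrom_lengths,
    site_gene = sample.int(g, s, replace = TRUE),
    topology_newick = nwk, seed = seed,
    params = list(events_per_branch = events_per_branch,
                  span_genes = span_genes, gene_bp = gene_bp)),
    class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("Clone tree:", x$m, "clones,", x$g, "genes,", x$s, "sites\n")
  cat("  topology:", x$topology_newick, "\n")
  invisible(x)
}

# per-unit true copy-number (genes x units) and expected dosage
# (sites x units) under a design
.unit_truth <- function(ct, design) {
  if (design$mode == "single_cell") {
    cn <- ct$clone_cn[, design$assignment, drop = FALSE]
    dos <- ct$clone_geno[, design$assignment, drop = FALSE]
  } else {
    w <- design$assignment                      # units x clones
    cn <- ct$clone_cn %*% t(w)                  # genes x units
    dos <- ct$clone_geno %*% t(w)
    cn <- sweep(cn, 2, design$purity, `*`) +
      matrix(2 * (1 - design$purity), nrow(cn), ncol(cn), byrow = TRUE)
    dos <- sweep(dos, 2, design$purity, `*`)
  }
  colnames(cn) <- colnames(dos) <- design$unit_names
  list(cn = cn, dosage = dos)
}

# run-length encode a per-gene CN vector into a segment table
.cn_to_segments <- function(cnv, annotation) {
  out <- lapply(unique(annotation$chrom), function(ch) {
    idx <- which(annotation$chrom == ch)
    r <- rle(cnv[idx])
    ends <- cumsum(r$lengths)
    starts <- c(1, head(ends, -1) + 1)
    data.frame(chrom = ch,
               start = annotation$start[idx[starts]],
               end = annotation$end[idx[ends]],
               total_cn = r$values)
  })
  do.call(rbind, out)
}

#' Observe the DNA channel of a simulated clone tree
#'
#' Single-cell mode: the cell genotype is its clone's genotype with
#' heterozygote dropout (a het site becomes hom-ref or hom-alt with equal
#' probability) at `ado_rate` and spurious het variants at `fp_rate`; the
#' cell CN profile is the clone profile plus integer-rounded Gaussian
#' jitter (floored at 0).  Bulk/spatial mode: the unit CN is the
#' purity-weighted clone-mixture copy number (real-valued, diploid
#' background for the normal fraction) and a variant is present when the
#' mixture expected dosage reaches `geno_threshold`.
#'
#' @param ct a [simulate_clone_tree()] result.
#' @param design a [sample_design()].
#' @param noise a [noise_config()].
#' @return list with `geno` (sites x units dosage), `cn` (genes x units)
#'   and `segments` (named list of per-unit segment tables in the
#'   coordinates of `ct$annotation`).
#' @export
observe_dna <- function(ct, design, noise = noise_config()) {
  tr <- .unit_truth(ct, design)
  n <- design$n_units
  geno <- tr$dosage
  cn <- tr$cn
  if (design$mode == "single_cell") {
    if (noise$ado_rate > 0) {
      het <- which(geno == 1)
      drop <- het[runif(length(het)) < noise$ado_rate]
      geno[drop] <- sample(c(0L, 2L), length(drop), replace = TRUE)
    }
    if (noise$fp_rate > 0) {
      ref <- which(geno == 0)
      fp <- ref[runif(length(ref)) < noise$fp_rate]
      geno[fp] <- 1L
    }
    if (noise$cn_jitter_sd > 0)
      cn <- pmax(cn + round(matrix(rnorm(length(cn), 0, noise$cn_jitter_sd),
                                   nrow(cn))), 0)
  } else {
    geno <- ifelse(geno >= noise$geno_threshold, 1L, 0L)
  }
  segs <- lapply(seq_len(n), function(u)
    .cn_to_segments(cn[, u], ct$annotation))
  names(segs) <- design$unit_names
  list(geno = geno, cn = cn, segments = segs)
}

#' Observe the RNA channel of a simulated clone tree
#'
#' Expression is dosage-coupled: the expected count of gene `j` in unit
#' `u` is `base_expr[j] * (CN[j, u] / 2) * libsize[u]`, drawn from a
#' negative binomial with dispersion `nb_dispersion` (variance
#' `mu + phi mu^2`), or rounded deterministically when
#' `nb_dispersion = 0` and `libsize_log_sd = 0`.  Variant-site read
#' totals follow a Poisson with mean `depth_mean` scaled by the site's
#' local relative CN and library size; alt reads are binomial in the
#' allele fraction `dosage / 2` (all deterministic rounded expectations
#' in the noise-free configuration).
#'
#' @inheritParams observe_dna
#' @param base_expr per-gene baseline mean expression; defaults to a
#'   fixed log-normal profile drawn from the current RNG stream.
#' @return list with `counts` (genes x units), `alt` and `total`
#'   (sites x units read counts) and `base_expr`.
#' @export
observe_rna <- function(ct, design, noise = noise_config(),
                        base_expr = NULL) {
  if (is.null(base_expr)) base_expr <- rlnorm(ct$g, meanlog = 2.5, sdlog = 1)
  stopifnot(length(base_expr) == ct$g, all(base_expr >= 0))
  tr <- .unit_truth(ct, design)
  n <- design$n_units
  stochastic <- noise$nb_dispersion > 0 || noise$libsize_log_sd > 0
  lib <- if (noise$libsize_log_sd > 0)
    exp(rnorm(n, 0, noise$libsize_log_sd)) else rep(1, n)
  mu <- sweep(base_expr * tr$cn / 2, 2, lib, `*`)
  counts <- if (noise$nb_dispersion > 0)
    matrix(rnbinom(length(mu), mu = mu, size = 1 / noise$nb_dispersion),
           nrow(mu)) else round(mu)
  dimnames(counts) <- list(ct$annotation$gene, design$unit_names)
  cn_site <- tr$cn[ct$site_gene, , drop = FALSE]
  depth_mu <- sweep(noise$depth_mean * cn_site / 2, 2, lib, `*`)
  total <- if (stochastic)
    matrix(rpois(length(depth_mu), depth_mu), nrow(depth_mu))
    else round(depth_mu)
  af <- pmin(tr$dosage / 2, 1)
  alt <- if (stochastic)
    matrix(rbinom(length(total), as.vector(total), as.vector(af)),
           nrow(total)) else round(total * af)
  dimnames(total) <- dimnames(alt) <-
    list(rownames(ct$clone_geno), design$unit_names)
  list(counts = counts, alt = alt, total = total, base_expr = base_expr)
}
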