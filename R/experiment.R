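#' Run a full simulate-build-compare experiment
#'
#' Generates (or accepts) a simulated bundle, builds the requested channel
#' trees, computes the adjusted Rand index of each tree's ground-truth-k
#' cut against the true population labels, and compares every channel pair
#' by tanglegram entanglement before and after two-sided untangling.
#' Everything is deterministic given `seed`.
#'
#' Channels:
#' * `gsnv` — identity-by-state on DNA genotypes, average linkage;
#' * `isnv` — depth-gated RNA variant divergence, `ward.D`;
#' * `gcnv` — segment binning + Euclidean/Ward ([gcnv_tree()]);
#' * `icnv` — expression-inferred CNV profile + Euclidean/Ward
#'   (spot counts are pseudo-bulked per section for the spatial preset);
#' * `trinary` — MED±SD trinarization + 3-state ML distance + UPGMA.
#'
#' @param preset preset name for [sim_preset()], or an existing
#'   `"sim_bundle"`.
#' @param seed master seed (ignored when a bundle is supplied).
#' @param channels subset of
#'   `c("gsnv", "isnv", "gcnv", "icnv", "trinary")`.
#' @param noise a [noise_config()].
#' @param L entanglement norm exponent.
#' @param bin_bp bin width for the gCNV channel.
#' @param icnv_window moving-average window for the iCNV channel.
#' @param out_dir optional directory; when given, trees (Newick),
#'   tanglegram SVGs and a JSON report are written there.
#' @return object of class `"concordance_report"`: list with `trees`
#'   (named dendrograms), `ari` (per channel), `pairs` (data.frame of
#'   pre/post entanglement per channel pair), `preset`, `seed`, `params`.
#' @export
run_experiment <- function(preset = "sidr_like", seed = 1,
                           channels = c("gsnv", "isnv", "gcnv", "icnv",
                                        "trinary"),
                           noise = noise_config(), L = 1.5,
                           bin_bp = 10000, icnv_window = 101,
                           out_dir = NULL) {
  channels <- match.arg(channels, several.ok = TRUE)
  bundle <- if (inherits(preset, "sim_bundle")) preset
            else sim_preset(preset, seed = seed, noise = noise)
  counts <- bundle$rna$counts
  alt <- bundle$rna$alt; total <- bundle$rna$total
  if (!is.null(bundle$section_of)) {
    counts <- pseudobulk(counts, bundle$section_of)
    # aggregate variant reads within sections for the RNA-SNV channel
    alt <- pseudobulk(alt, bundle$section_of)
    total <- pseudobulk(total, bundle$section_of)
  }
  trees <- list()
  for (ch in channels) {
    trees[[ch]] <- switch(ch,
      gsnv = build_snv_tree(ibs_matrix(bundle$dna$geno), "average"),
      isnv = build_snv_tree(rna_divergence(alt, total), "ward.D"),
      gcnv = gcnv_tree(bundle$dna$segments, bin_bp = bin_bp,
                       chrom_lengths = bundle$chrom_lengths),
      icnv = build_icnv_tree(
        infer_cnv_profile(counts, bundle$annotation,
                          window = icnv_window)),
      trinary = build_trinary_tree(counts))
  }
  truth <- bundle$truth
  ari <- vapply(trees, function(t) {
    part <- cutree(stats::as.hclust(t), k = bundle$k)
    mclust::adjustedRandIndex(part[names(truth)], truth)
  }, numeric(1))
  pairs <- NULL
  if (length(channels) >= 2) {
    cmb <- combn(channels, 2)
    pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      a <- cmb[1, i]; b <- cmb[2, i]
      tg <- tanglegram(trees[[a]], trees[[b]], L = L,
                       untangle = "step2side")
      data.frame(left = a, right = b,
                 entanglement_pre = tg$pre_entanglement,
                 entanglement_post = tg$entanglement,
                 rounds = tg$rounds)
    }))
  }
  report <- structure(list(
    preset = bundle$name, seed = bundle$seed, channels = channels,
    trees = trees, ari = ari, pairs = pairs, k = bundle$k,
    params = list(L = L, bin_bp = bin_bp, icnv_window = icnv_window,
                  noise = unclass(bundle$noise))),
    class = "concordance_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (ch in channels)
      writeLines(write_newick(trees[[ch]]),
                 file.path(out_dir, paste0(ch, ".nwk")))
    if (!is.null(pairs))
      for (i in seq_len(nrow(pairs))) {
        tg <- tanglegram(trees[[pairs$left[i]]], trees[[pairs$right[i]]],
                         L = L, untangle = "step2side")
        grp <- if (!is.null(truth)) truth else NULL
        try(render_tanglegram(
          tg, file.path(out_dir, paste0(pairs$left[i], "_vs_",
                                        pairs$right[i], ".svg")),
          col_by = grp), silent = TRUE)
      }
    jsonlite::write_json(
      list(preset = report$preset, seed = report$seed,
           channels = channels, ari = as.list(ari),
           pairs = pairs, params = report$params),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  report
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Concordance report — preset '", x$preset, "', seed ", x$seed,
      "\n", sep = "")
  cat("  ARI at k =", x$k, ":",
      paste(sprintf("%s=%.3f", names(x$ari), x$ari), collapse = ", "), "\n")
  if (!is.null(x$pairs)) {
    cat("  entanglement (pre -> post step2side):\n")
    for (i in seq_len(nrow(x$pairs)))
      cat(sprintf("    %s vs %s: %.4f -> %.4f\n", x$pairs$left[i],
                  x$pairs$right[i], x$pairs$entanglement_pre[i],
                  x$pairs$entanglement_post[i]))
  }
  invisible(x)
}

#' Validate an input bundle on disk
#'
#' Schema checks for the plain-text interchange files; returns a character
#' vector of diagnostics (empty = all well-formed).  Checked when
#' supplied: `counts` (TSV, numeric, non-negative), `annotation` (TSV
#' covering every counted gene), `segments` (directory of per-sample
#' TSVs, coordinates within `chrom_lengths`), `chrom_lengths` (TSV),
#' `newick` (parses as a binary tree).
#'
#' @param paths named list of file/directory paths; any subset of
#'   `counts`, `annotation`, `segments`, `chrom_lengths`, `newick`.
#' @return character vector of diagnostic messages.
#' @export
validate_inputs <- function(paths) {
  diag <- character(0)
  note <- function(...) diag <<- c(diag, paste0(...))
  counts <- NULL
  if (!is.null(paths$counts)) {
    if (!file.exists(paths$counts)) note("counts: file not found: ", paths$counts)
    else {
      counts <- try(as.matrix(read.delim(paths$counts, row.names = 1,
                                         check.names = FALSE)), silent = TRUE)
      if (inherits(counts, "try-error")) {
        note("counts: unreadable TSV"); counts <- NULL
      } else if (!is.numeric(counts)) {
        note("counts: non-numeric entries"); counts <- NULL
      } else if (any(counts < 0)) note("counts: negative values")
    }
  }
  ann <- NULL
  if (!is.null(paths$annotation)) {
    ann <- try(read.delim(paths$annotation), silent = TRUE)
    if (inherits(ann, "try-error")) { note("annotation: unreadable TSV"); ann <- NULL }
    else {
      need <- c("gene", "chrom", "start", "end")
      if (!all(need %in% names(ann)))
        note("annotation: missing column(s) ",
             paste(setdiff(need, names(ann)), collapse = ", "))
      else if (!is.null(counts)) {
        miss <- setdiff(rownames(counts), ann$gene)
        if (length(miss)) note("annotation: counted gene(s) not annotated: ",
                               paste(head(miss, 5), collapse = ", "))
      }
    }
  }
  lens <- NULL
  if (!is.null(paths$chrom_lengths)) {
    cl <- try(read.delim(paths$chrom_lengths), silent = TRUE)
    if (inherits(cl, "try-error") || !all(c("chrom", "length") %in% names(cl)))
      note("chrom_lengths: need columns chrom, length")
    else lens <- setNames(cl$length, cl$chrom)
  }
  if (!is.null(paths$segments)) {
    files <- if (dir.exists(paths$segments))
      list.files(paths$segments, "\\.tsv$", full.names = TRUE)
      else paths$segments
    if (!length(files)) note("segments: no TSV files in ", paths$segments)
    for (f in files) {
      s <- try(read.delim(f), silent = TRUE)
      if (inherits(s, "try-error") ||
          !all(c("chrom", "start", "end", "total_cn") %in% names(s))) {
        note("segments: ", basename(f),
             ": need columns chrom, start, end, total_cn")
        next
      }
      if (any(s$end < s$start))
        note("segments: ", basename(f), ": end before start at line(s) ",
             paste(which(s$end < s$start) + 1, collapse = ", "))
      if (!is.null(lens)) {
        known <- s$chrom %in% names(lens)
        if (!all(known))
          note("segments: ", basename(f), ": unknown chromosome(s) ",
               paste(unique(s$chrom[!known]), collapse = ", "))
        over <- known & s$end > lens[as.character(s$chrom)]
        if (any(over))
          note("segments: ", basename(f), ": segment(s) past chromosome end: ",
               paste(sprintf("%s:%d-%d", s$chrom[over], s$start[over],
                             s$end[over]), collapse = "; "))
      }
    }
  }
  if (!is.null(paths$newick)) {
    txt <- try(paste(readLines(paths$newick, warn = FALSE), collapse = ""),
               silent = TRUE)
    if (inherits(txt, "try-error")) note("newick: unreadable file")
    else {
      t <- try(read_newick(txt), silent = TRUE)
      if (inherits(t, "try-error"))
        note("newick: ", conditionMessage(attr(t, "condition")))
    }
  }
  diag
}
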