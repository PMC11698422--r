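#' Tanglegram entanglement between two dendrograms
#'
#' The concordance statistic used throughout the package.  Each label
#' shared by the two trees has a rank in the left tree's leaf order and a
#' rank in the right tree's leaf order (ranks are taken after restricting
#' both orders to the shared label set).  With `r_i`, `s_i` those ranks,
#'
#' \deqn{E = \frac{\sum_i |r_i - s_i|^L}{\sum_i |i - (n+1-i)|^L}}
#'
#' i.e. the rank-difference norm normalized by its value for a full
#' reversal, so `E = 0` means the shared leaves appear in identical order
#' (no crossing connectors) and `E = 1` means the orders are exactly
#' reversed (maximal entanglement).  `L` is the norm exponent; 1.5 is the
#' conventional default.
#'
#' @param left,right binary [stats::dendrogram] objects with unique leaf
#'   labels and at least 2 labels in common.
#' @param L positive norm exponent.
#' @return entanglement value in `[0, 1]`.
#' @examples
#' t <- upgma(dist_matrix(matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'        dimnames = list(c("A", "B", "C"), c("A", "B", "C")))))
#' entanglement(t, t)  # 0
#' @export
entanglement <- function(left, right, L = 1.5) {
  stopifnot(is.numeric(L), L > 0)
  lo <- leaf_order(left); ro <- leaf_order(right)
  if (anyDuplicated(lo) || anyDuplicated(ro))
    stop("duplicate leaf labels within a tree")
  shared <- intersect(lo, ro)
  if (length(shared) == 0) stop("trees share no leaf labels")
  n <- length(shared)
  if (n < 2) return(0)
  lres <- lo[lo %in% shared]          # shared labels in left display order
  rres <- ro[ro %in% shared]
  r <- seq_len(n)                     # rank of lres[i] in left = i
  s <- match(lres, rres)              # rank of the same label in right
  raw <- sum(abs(r - s)^L)
  mx <- sum(abs(seq_len(n) - (n + 1 - seq_len(n)))^L)
  if (mx == 0) return(0)
  raw / mx
}

# Flatten a dendrogram into indexed arrays for the untangling DP.
flatten_dend <- function(t) {
  kids <- list(); labs <- character(0); hts <- numeric(0); sup <- list()
  add <- function(node) {
    if (is.leaf(node)) {
      kids[length(kids) + 1L] <<- list(NULL)
      labs[length(kids)] <<- attr(node, "label")
      hts[length(kids)] <<- attr(node, "height")
      sup[[length(kids)]] <<- NA
      return(length(kids))
    }
    a <- add(node[[1]]); b <- add(node[[2]])
    kids[[length(kids) + 1L]] <<- c(a, b)
    labs[length(kids)] <<- NA_character_
    hts[length(kids)] <<- attr(node, "height")
    s <- attr(node, "support")
    sup[[length(kids)]] <<- if (is.null(s)) NA else s
    length(kids)
  }
  root <- add(t)
  list(kids = kids, labs = labs, hts = hts, sup = sup, root = root)
}

#' One-sided exact untangling
#'
#' Rotates internal nodes of `movable` (children swaps only; topology and
#' heights untouched) so that its entanglement against the fixed tree is
#' minimal over *all* `2^(n-1)` rotations.  Because the rank-difference sum
#' decomposes over the contiguous leaf blocks of subtrees, the optimum is
#' found by dynamic programming over (node, rank offset) pairs in
#' `O(n^2)` — no greedy search, so the result is the true one-sided
#' minimum.  Ties prefer the original child order, and the entanglement of
#' the returned tree never exceeds the input entanglement.
#'
#' @param fixed dendrogram held fixed.
#' @param movable dendrogram whose nodes are rotated.
#' @param L norm exponent, as in [entanglement()].
#' @return rotated copy of `movable`.
#' @export
untangle_step1side <- function(fixed, movable, L = 1.5) {
  shared <- intersect(leaf_order(fixed), leaf_order(movable))
  if (length(shared) < 2) return(movable)
  fres <- leaf_order(fixed)
  fres <- fres[fres %in% shared]
  target <- setNames(seq_along(fres), fres)   # rank each shared label must hit
  fl <- flatten_dend(movable)
  nshared <- integer(length(fl$kids))
  for (i in seq_along(fl$kids)) {
    k <- fl$kids[[i]]
    nshared[i] <- if (is.null(k)) as.integer(fl$labs[i] %in% shared)
                  else nshared[k[1]] + nshared[k[2]]
  }
  memo <- new.env(parent = emptyenv())
  solve_node <- function(id, offset) {
    key <- paste0(id, ":", offset)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    k <- fl$kids[[id]]
    res <- if (is.null(k)) {
      lab <- fl$labs[id]
      cost <- if (lab %in% shared) abs((offset + 1) - target[[lab]])^L else 0
      list(cost = cost, flip = FALSE)
    } else {
      keep <- solve_node(k[1], offset)$cost +
              solve_node(k[2], offset + nshared[k[1]])$cost
      swap <- solve_node(k[2], offset)$cost +
              solve_node(k[1], offset + nshared[k[2]])$cost
      if (swap < keep - 1e-12) list(cost = swap, flip = TRUE)
      else list(cost = keep, flip = FALSE)
    }
    memo[[key]] <- res
    res
  }
  solve_node(fl$root, 0L)
  rebuild <- function(id, offset) {
    k <- fl$kids[[id]]
    if (is.null(k)) {
      leaf <- 1L
      attributes(leaf) <- list(members = 1L, height = fl$hts[id],
                               label = fl$labs[id], leaf = TRUE)
      return(leaf)
    }
    flip <- memo[[paste0(id, ":", offset)]]$flip
    ord <- if (flip) c(k[2], k[1]) else k
    a <- rebuild(ord[1], offset)
    b <- rebuild(ord[2], offset + nshared[ord[1]])
    node <- list(a, b)
    attributes(node) <- list(
      members = attr(a, "members") + attr(b, "members"),
      height = fl$hts[id], class = "dendrogram")
    if (!is.na(fl$sup[[id]])) attr(node, "support") <- fl$sup[[id]]
    node
  }
  fix_midpoints(rebuild(fl$root, 0L))
}

# Rebuild a dendrogram from its flattened form with a logical flip vector
# indexed over internal nodes (in flatten_dend order).
apply_flips <- function(fl, flips) {
  internal <- which(!vapply(fl$kids, is.null, logical(1)))
  flip_of <- setNames(rep(FALSE, length(fl$kids)), seq_along(fl$kids))
  flip_of[internal] <- flips
  rec <- function(id) {
    k <- fl$kids[[id]]
    if (is.null(k)) {
      leaf <- 1L
      attributes(leaf) <- list(members = 1L, height = fl$hts[id],
                               label = fl$labs[id], leaf = TRUE)
      return(leaf)
    }
    if (flip_of[[id]]) k <- c(k[2], k[1])
    a <- rec(k[1]); b <- rec(k[2])
    node <- list(a, b)
    attributes(node) <- list(
      members = attr(a, "members") + attr(b, "members"),
      height = fl$hts[id], class = "dendrogram")
    if (!is.na(fl$sup[[id]])) attr(node, "support") <- fl$sup[[id]]
    node
  }
  fix_midpoints(rec(fl$root))
}

#' Two-sided untangling
#'
#' Minimizes the entanglement over simultaneous rotations of both trees.
#' Two regimes, chosen automatically:
#'
#' * **Exact** (default when the smaller tree has at most
#'   `exhaustive_max_nodes` internal nodes): every rotation of the smaller
#'   tree is enumerated and, for each, the other tree is solved exactly by
#'   the one-sided dynamic program — the returned pair attains the global
#'   minimum over all rotation pairs.
#' * **Alternating** (larger trees): exact one-sided passes
#'   ([untangle_step1side()]) alternate between the trees until a round no
#'   longer improves or `max_rounds` is reached; the alternation is run
#'   from both start orders and the better final pair kept.
#'
#' In both regimes the final entanglement never exceeds the initial one.
#'
#' @param left,right dendrograms.
#' @param L norm exponent.
#' @param max_rounds cap on alternation rounds per start order.
#' @param exhaustive_max_nodes enumeration budget: largest internal-node
#'   count of the smaller tree for which the exact regime is used
#'   (2^nodes one-sided solves).
#' @return list with elements `left`, `right`, `entanglement`, `rounds`.
#' @export
untangle_step2side <- function(left, right, L = 1.5, max_rounds = 25,
                               exhaustive_max_nodes = 12) {
  n_small <- min(length(leaf_order(left)), length(leaf_order(right)))
  if (n_small - 1 <= exhaustive_max_nodes) {
    small_is_left <- length(leaf_order(left)) <= length(leaf_order(right))
    small <- if (small_is_left) left else right
    other <- if (small_is_left) right else left
    fl <- flatten_dend(small)
    k <- sum(!vapply(fl$kids, is.null, logical(1)))
    best <- NULL
    for (mask in 0:(2^k - 1)) {
      flips <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
      sv <- apply_flips(fl, flips)
      ov <- untangle_step1side(sv, other, L)
      e <- entanglement(sv, ov, L)
      if (is.null(best) || e < best$e - 1e-12) best <- list(e = e, s = sv, o = ov)
      if (best$e <= 1e-12) break
    }
    out <- if (small_is_left) list(left = best$s, right = best$o)
           else list(left = best$o, right = best$s)
    out$entanglement <- best$e
    out$rounds <- 1L
    stopifnot(out$entanglement <= entanglement(left, right, L) + 1e-12)
    return(out)
  }
  one_run <- function(a, b, b_first) {
    ent <- entanglement(a, b, L)
    rounds <- 0L
    repeat {
      if (b_first) {
        b <- untangle_step1side(a, b, L)
        a <- untangle_step1side(b, a, L)
      } else {
        a <- untangle_step1side(b, a, L)
        b <- untangle_step1side(a, b, L)
      }
      e2 <- entanglement(a, b, L)
      rounds <- rounds + 1L
      stopifnot(e2 <= ent + 1e-12)
      if (e2 >= ent - 1e-12 || rounds >= max_rounds) {
        ent <- min(ent, e2)
        break
      }
      ent <- e2
    }
    list(left = a, right = b, entanglement = ent, rounds = rounds)
  }
  r1 <- one_run(left, right, b_first = TRUE)
  r2 <- one_run(left, right, b_first = FALSE)
  if (r2$entanglement < r1$entanglement - 1e-12) r2 else r1
}

#' Tanglegram object: paired trees plus their entanglement
#'
#' Bundles two dendrograms, optionally untangles them, and records the
#' entanglement before and after.  `plot()` draws the classic back-to-back
#' layout with straight connectors between shared labels;
#' [render_tanglegram()] writes it to an SVG/PDF/PNG file.
#'
#' @param left,right dendrograms.
#' @param L norm exponent for [entanglement()].
#' @param untangle `"none"`, `"step1side"` (rotate `right` only) or
#'   `"step2side"`.
#' @return object of class `"tanglegram"`: list with `left`, `right`, `L`,
#'   `entanglement` (post-untangle), `pre_entanglement`, `rounds`,
#'   `shared` (shared label count).
#' @export
tanglegram <- function(left, right, L = 1.5,
                       untangle = c("none", "step1side", "step2side")) {
  untangle <- match.arg(untangle)
  pre <- entanglement(left, right, L)
  rounds <- 0L
  if (untangle == "step1side") {
    right <- untangle_step1side(left, right, L)
    rounds <- 1L
  } else if (untangle == "step2side") {
    u <- untangle_step2side(left, right, L)
    left <- u$left; right <- u$right; rounds <- u$rounds
  }
  structure(list(
    left = left, right = right, L = L,
    entanglement = entanglement(left, right, L),
    pre_entanglement = pre, rounds = rounds, untangle = untangle,
    shared = length(intersect(leaf_order(left), leaf_order(right)))),
    class = "tanglegram")
}

#' @export
print.tanglegram <- function(x, ...) {
  cat("Tanglegram:", length(leaf_order(x$left)), "vs",
      length(leaf_order(x$right)), "leaves,", x$shared, "shared\n")
  cat(sprintf("  entanglement = %.4g (L = %g)\n", x$entanglement, x$L))
  if (x$untangle != "none")
    cat(sprintf("  before %s untangling: %.4g (%d rounds)\n",
                x$untangle, x$pre_entanglement, x$rounds))
  invisible(x)
}

#' @export
plot.tanglegram <- function(x, col_by = NULL, main = NULL,
                            connector_lwd = 1.5, ...) {
  op <- par(no.readonly = TRUE)
  on.exit({ par(op); layout(1) })
  lo <- leaf_order(x$left); ro <- leaf_order(x$right)
  n <- max(length(lo), length(ro))
  ylim <- c(0.5, n + 0.5)
  layout(matrix(1:3, 1), widths = c(2, 1.4, 2))
  par(mar = c(2, 0.5, 3, 0))
  plot(x$left, horiz = TRUE, leaflab = "none", yaxs = "i", ylim = ylim,
       xlim = c(attr(x$left, "height"), 0), axes = FALSE)
  par(mar = c(2, 0, 3, 0))
  plot.new()
  plot.window(xlim = c(0, 1), ylim = ylim, yaxs = "i")
  cols <- rep("grey40", length(lo))
  if (!is.null(col_by)) {
    grp <- col_by[lo]
    pal <- grDevices::hcl.colors(max(1L, length(unique(stats::na.omit(col_by)))),
                                 "Dark 3")
    cols <- pal[as.integer(factor(grp, levels = unique(stats::na.omit(col_by))))]
    cols[is.na(cols)] <- "grey40"
  }
  for (i in seq_along(lo)) {
    j <- match(lo[i], ro)
    if (!is.na(j))
      segments(0.02, i, 0.98, j, col = cols[i], lwd = connector_lwd)
    text(0.02, i, lo[i], adj = c(0, 0.5), cex = 0.6, col = cols[i])
  }
  for (j in seq_along(ro))
    if (!(ro[j] %in% lo))
      text(0.98, j, ro[j], adj = c(1, 0.5), cex = 0.6, col = "grey70")
  if (is.null(main))
    main <- sprintf("entanglement = %.3f (L = %g)", x$entanglement, x$L)
  graphics::mtext(main, side = 3, line = 1, cex = 0.8)
  par(mar = c(2, 0, 3, 0.5))
  plot(x$right, horiz = TRUE, leaflab = "none", yaxs = "i", ylim = ylim,
       xlim = c(0, attr(x$right, "height")), axes = FALSE)
  invisible(x)
}

#' Render a tanglegram to an image file
#'
#' Device chosen from the file extension (`.svg`, `.pdf`, `.png`).
#'
#' @param tg a [tanglegram()] object.
#' @param path output file.
#' @param width,height device size in inches (pixels / 100 for PNG).
#' @param ... passed to `plot.tanglegram`.
#' @return `path`, invisibly.
#' @export
render_tanglegram <- function(tg, path, width = 9, height = 6, ...) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    svg = svg(path, width = width, height = height),
    pdf = pdf(path, width = width, height = height),
    png = png(path, width = 100 * width, height = 100 * height),
    stop("unsupported extension '", ext, "' (use svg/pdf/png)"))
  on.exit(dev.off())
  plot(tg, ...)
  invisible(path)
}
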