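#' Newick import and export for dendrograms
#'
#' The package stores trees height-based (leaves at height 0, internal
#' nodes at their merge height), so on export the branch length of a child
#' is `height(parent) - height(child)` and internal-node bootstrap support
#' values (attribute `"support"`, if present) are written as internal node
#' labels.  On import, node heights are reconstructed as the maximum
#' root-to-leaf path below each node, which inverts the writer exactly for
#' any tree the package produces (monotone heights); a non-ultrametric
#' foreign tree is accepted but its per-branch lengths are flattened onto
#' this height scale.
#'
#' Only binary trees are supported.  Multifurcating input is rejected
#' unless `binarize = TRUE`, in which case nodes are resolved left-leaning
#' with zero-length internal edges.  Malformed input raises an error
#' naming the 1-based character offset.
#'
#' @param text a Newick string (single tree, terminated by `;`).
#' @param binarize resolve multifurcations left-leaning instead of failing.
#' @return `read_newick()`: a [stats::dendrogram]; `write_newick()`: a
#'   Newick string.
#' @examples
#' t <- read_newick("((A:1,B:1):1,C:2);")
#' leaf_order(t)                      # "A" "B" "C"
#' write_newick(t)                    # round-trips
#' @export
read_newick <- function(text, binarize = FALSE) {
  chars <- strsplit(text, "")[[1]]
  pos <- 1L
  n <- length(chars)
  peek <- function() if (pos <= n) chars[pos] else ""
  fail <- function(msg) stop(sprintf("Newick parse error at offset %d: %s",
                                     pos, msg), call. = FALSE)
  skip_ws <- function() while (pos <= n && chars[pos] %in% c(" ", "\t", "\n", "\r"))
    pos <<- pos + 1L
  read_label <- function() {
    start <- pos
    while (pos <= n && !(chars[pos] %in% c(",", "(", ")", ":", ";")))
      pos <<- pos + 1L
    if (pos == start) "" else
      trimws(paste(chars[start:(pos - 1L)], collapse = ""))
  }
  read_length <- function() {
    start <- pos
    while (pos <= n && (chars[pos] %in% c("0","1","2","3","4","5","6","7",
                                          "8","9",".","-","+","e","E")))
      pos <<- pos + 1L
    if (pos == start) fail("expected branch length after ':'")
    v <- suppressWarnings(as.numeric(paste(chars[start:(pos - 1L)],
                                           collapse = "")))
    if (is.na(v)) fail("invalid branch length")
    v
  }
  parse_clade <- function() {
    skip_ws()
    node <- if (peek() == "(") {
      pos <<- pos + 1L
      kids <- list(parse_clade())
      while (peek() == ",") { pos <<- pos + 1L; kids <- c(kids, list(parse_clade())) }
      if (peek() != ")") fail("expected ')' or ','")
      pos <<- pos + 1L
      lab <- read_label()
      list(children = kids, label = lab)
    } else {
      lab <- read_label()
      if (!nzchar(lab)) fail("expected a leaf label")
      list(children = NULL, label = lab)
    }
    node$length <- if (peek() == ":") { pos <<- pos + 1L; read_length() } else NA_real_
    skip_ws()
    node
  }
  root <- parse_clade()
  if (peek() != ";") fail("expected ';'")
  # height of each raw node = max path length to a descendant leaf
  height_of <- function(nd) {
    if (is.null(nd$children)) return(0)
    max(vapply(nd$children, function(k) {
      bl <- if (is.na(k$length)) 0 else k$length
      height_of(k) + bl
    }, numeric(1)))
  }
  to_dend <- function(nd) {
    if (is.null(nd$children)) {
      leaf <- 1L
      attributes(leaf) <- list(members = 1L, height = 0,
                               label = nd$label, leaf = TRUE)
      return(leaf)
    }
    kids <- nd$children
    if (length(kids) > 2) {
      if (!binarize)
        stop("non-binary node (", length(kids),
             " children); set binarize = TRUE to resolve", call. = FALSE)
      while (length(kids) > 2) {
        merged <- list(children = kids[1:2], label = "", length = 0)
        kids <- c(list(merged), kids[-(1:2)])
      }
    }
    if (length(kids) < 2) stop("node with a single child", call. = FALSE)
    node <- lapply(kids, to_dend)
    h <- height_of(nd)
    # recompute child heights consistently with this node's height
    attributes(node) <- list(
      members = sum(vapply(node, function(x) attr(x, "members"), integer(1))),
      height = h, class = "dendrogram")
    sup <- suppressWarnings(as.numeric(nd$label))
    if (length(sup) == 1 && !is.na(sup)) attr(node, "support") <- sup
    node
  }
  d <- to_dend(root)
  labs <- leaf_labels_dend(d)
  if (anyDuplicated(labs)) stop("duplicate leaf labels in tree", call. = FALSE)
  fix_midpoints(d)
}

#' @rdname read_newick
#' @param t a binary [stats::dendrogram].
#' @param digits significant digits for branch lengths.
#' @export
write_newick <- function(t, digits = 10) {
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  rec <- function(node, parent_h) {
    bl <- parent_h - attr(node, "height")
    if (is.leaf(node))
      return(paste0(attr(node, "label"), ":", fmt(bl)))
    h <- attr(node, "height")
    sup <- attr(node, "support")
    paste0("(", rec(node[[1]], h), ",", rec(node[[2]], h), ")",
           if (!is.null(sup)) fmt(sup) else "", ":", fmt(bl))
  }
  if (is.leaf(t)) return(paste0(attr(t, "label"), ";"))
  h <- attr(t, "height")
  sup <- attr(t, "support")
  paste0("(", rec(t[[1]], h), ",", rec(t[[2]], h), ")",
         if (!is.null(sup)) fmt(sup) else "", ";")
}

# leaf labels without requiring midpoints (used during parsing)
leaf_labels_dend <- function(t) {
  out <- character(0)
  walk <- function(node) {
    if (is.leaf(node)) out <<- c(out, attr(node, "label"))
    else { walk(node[[1]]); walk(node[[2]]) }
  }
  walk(t)
  out
}
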