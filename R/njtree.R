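#' Pairwise p-distance matrix from aligned sequences
#'
#' `d[i, j]` is mismatches over compared columns; columns with a gap (`-`)
#' or `N` in either sequence are excluded from the comparison. A
#' Jukes-Cantor correction is available behind the `model` flag (the default
#' is the uncorrected proportion).
#'
#' @param aligned Tibble with `id` and `sequence` columns, or a named
#'   character vector, of equal-length aligned sequences (>= 2 taxa).
#' @param model `"p"` (default) or `"JC"`.
#' @return A symmetric numeric matrix with taxa dimnames.
#' @export
p_distance <- function(aligned, model = c("p", "JC")) {
  model <- match.arg(model)
  if (is.data.frame(aligned)) {
    ids <- aligned$id
    seqs <- toupper(aligned$sequence)
  } else {
    ids <- names(aligned)
    seqs <- toupper(unname(aligned))
  }
  n <- length(seqs)
  if (n < 2) abort("need at least 2 taxa")
  if (length(unique(nchar(seqs))) != 1) {
    abort("aligned sequences must have equal length")
  }
  chars <- do.call(rbind, strsplit(seqs, ""))
  valid <- chars %in% c("A", "C", "G", "T")
  dim(valid) <- dim(chars)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- valid[i, ] & valid[j, ]
      if (!any(ok)) {
        abort(paste0("no comparable columns between ", ids[i], " and ", ids[j]))
      }
      p <- sum(chars[i, ok] != chars[j, ok]) / sum(ok)
      if (model == "JC") {
        if (p >= 0.75) abort("p-distance too large for Jukes-Cantor correction")
        p <- -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q-criterion is joined (ties broken by the lowest (row, column) index pair
#' for determinism), branch lengths follow the standard formulas, and the
#' matrix is reduced until three nodes remain, which are joined in a root
#' trifurcation. The returned tree is unrooted. Negative branch lengths are
#' clamped to zero with the deficit moved to the sibling branch, preserving
#' the path length between the joined nodes.
#'
#' @param d Symmetric distance matrix with taxa dimnames (>= 3 taxa, zero
#'   diagonal, finite entries).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d)) d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) abort("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) abort("distance matrix must be symmetric")
  if (any(!is.finite(d))) abort("distance matrix entries must be finite")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  frag <- labels # newick fragment per active node
  act <- d
  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  fmt <- function(x) sprintf("%.12g", x)
  while (nrow(act) > 3) {
    r <- nrow(act)
    rs <- rowSums(act)
    q <- (r - 2) * act - outer(rs, rs, "+")
    diag(q) <- Inf
    # lowest (row, column) pair among the minima
    min_q <- min(q)
    hits <- which(q - min_q <= 1e-12 * max(1, abs(min_q)), arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    li <- act[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- act[i, j] - li
    ll <- clamp_pair(li, lj)
    new_frag <- paste0("(", frag[i], ":", fmt(ll[1]), ",",
                       frag[j], ":", fmt(ll[2]), ")")
    others <- setdiff(seq_len(r), c(i, j))
    new_d <- (act[i, others] + act[j, others] - act[i, j]) / 2
    act <- act[others, others, drop = FALSE]
    act <- rbind(cbind(act, new_d), c(new_d, 0))
    frag <- c(frag[others], new_frag)
  }
  # final trifurcation: three branch lengths solve the pairwise equations
  l1 <- (act[1, 2] + act[1, 3] - act[2, 3]) / 2
  l2 <- act[1, 2] - l1
  l3 <- act[1, 3] - l1
  for (idx in 1:3) { # clamp, deficit to the next branch
    ls <- c(l1, l2, l3)
    if (ls[idx] < 0) {
      nxt <- idx %% 3 + 1
      ls[nxt] <- ls[nxt] + ls[idx]
      ls[idx] <- 0
      l1 <- ls[1]; l2 <- ls[2]; l3 <- ls[3]
    }
  }
  nwk <- paste0("(", frag[1], ":", fmt(l1), ",", frag[2], ":", fmt(l2),
                ",", frag[3], ":", fmt(l3), ");")
  ape::read.tree(text = nwk)
}

#' Root a tree by outgroup or at the midpoint
#'
#' Outgroup mode places the root on the branch separating a monophyletic
#' outgroup from the ingroup; a non-monophyletic outgroup is an error naming
#' the offending taxa. Midpoint mode roots at the midpoint of the longest
#' leaf-to-leaf path.
#'
#' @param tree A `phylo` object.
#' @param outgroup Character vector of outgroup taxa; `NULL` (default) for
#'   midpoint rooting.
#' @return A rooted `phylo` object.
#' @export
root_tree <- function(tree, outgroup = NULL) {
  if (is.null(outgroup)) return(phangorn::midpoint(tree))
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing)) {
    abort(paste0("outgroup taxa not in tree: ", paste(missing, collapse = ", ")))
  }
  if (setequal(outgroup, tree$tip.label)) {
    abort("outgroup cannot contain every taxon")
  }
  if (length(outgroup) > 1 && !ape::is.monophyletic(tree, outgroup)) {
    abort(paste0("outgroup is not monophyletic: no split separates {",
                 paste(outgroup, collapse = ", "), "} from the ingroup"))
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] and [ape::write.tree()].
#'
#' @param path Newick file path.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`
#'   invisibly.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}

#' Path-length (patristic) distance matrix of a tree
#'
#' Used to verify the additivity property of neighbor joining.
#'
#' @param tree A `phylo` object.
#' @return Symmetric matrix of leaf-to-leaf path lengths, ordered by the
#'   sorted tip labels.
#' @export
tree_distances <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  ord <- sort(rownames(m))
  m[ord, ord]
}
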