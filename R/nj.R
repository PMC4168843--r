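#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou–Nei agglomeration: at each step join the pair (i, j)
#' minimizing the Q-criterion
#' `Q(i,j) = (r - 2) * d(i,j) - R_i - R_j`
#' (with `r` active nodes and `R_i` the row sum of i), attach the joined
#' nodes with the two-point branch lengths
#' `l_i = d(i,j)/2 + (R_i - R_j) / (2 (r - 2))`, `l_j = d(i,j) - l_i`,
#' and replace them by a node at distance
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2` from every other node.
#' Ties in Q are broken by the smallest (i, j) node-index pair (tips in
#' input order, then internal nodes in creation order). On an additive
#' (tree-like) matrix the result reproduces the generating tree exactly.
#'
#' Negative branch lengths — possible on non-additive matrices — are by
#' default clamped to zero with the deficit moved to the sister branch,
#' preserving the path length between the joined nodes
#' (Kuhner–Felsenstein convention).
#'
#' @param dmat a `k2p_dist` from [pairwise_distance_matrix()], or a
#'   complete symmetric numeric matrix with dimnames.
#' @param clamp_negative clamp negative branch lengths (default `TRUE`).
#' @return an unrooted tree of class `phylo` (ape).
#' @export
neighbor_joining <- function(dmat, clamp_negative = TRUE) {
  if (inherits(dmat, "k2p_dist")) {
    D <- dmat$d
  } else {
    D <- as.matrix(dmat)
  }
  labels <- rownames(D)
  n <- nrow(D)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("distance matrix must have non-empty row labels", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate labels in distance matrix", call. = FALSE)
  }
  if (n < 3L) stop("neighbor joining needs >= 3 taxa", call. = FALSE)
  bad <- which(!is.finite(D) & upper.tri(D), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    pairs <- apply(utils::head(bad, 10L), 1L, function(r) {
      paste0(labels[r[1L]], "/", labels[r[2L]])
    })
    stop("distance matrix has ", nrow(bad),
         " missing or saturated entries (e.g. ", paste(pairs, collapse = ", "),
         "); drop or impute them first (see drop_incomplete())", call. = FALSE)
  }

  # active nodes carry a node index (tie-break order) and a newick fragment
  frag <- vapply(labels, quote_newick_label, character(1L))
  node_id <- seq_len(n)
  next_id <- n + 1L
  repeat {
    r <- nrow(D)
    if (r == 3L) break
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    # node_id is ascending along the active vector, so lexicographic
    # (row, col) order equals the smallest node-index pair tie-break
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    if (clamp_negative) {
      if (li < 0) { lj <- lj + li; li <- 0 }
      if (lj < 0) { li <- li + lj; lj <- 0 }
      li <- max(li, 0); lj <- max(lj, 0)
    }
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], format_brlen(li),
                        frag[j], format_brlen(lj))
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    D <- D2
    frag <- c(frag[keep], new_frag)
    node_id <- c(node_id[keep], next_id)
    next_id <- next_id + 1L
  }
  # final unrooted trifurcation: three-point branch lengths
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  if (clamp_negative) { l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0) }
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    frag[1], format_brlen(l1), frag[2], format_brlen(l2),
                    frag[3], format_brlen(l3))
  ape::read.tree(text = newick)
}

format_brlen <- function(x) sprintf("%.15g", x)

quote_newick_label <- function(lab) {
  if (grepl("[ ()\\[\\]:;,']", lab)) {
    paste0("'", gsub("'", "''", lab), "'")
  } else {
    lab
  }
}

#' Drop sequences until the distance matrix is complete
#'
#' Greedy policy for matrices with missing or saturated pairs: while
#' any off-diagonal entry is non-finite, drop the label involved in the
#' most such entries (ties broken by label order). Returns the reduced
#' matrix and the dropped labels, so the pruning can be reported.
#'
#' @param dmat a `k2p_dist` or a symmetric numeric matrix with dimnames.
#' @return list with `d` (complete numeric matrix) and `dropped`
#'   (character vector of removed labels).
#' @export
drop_incomplete <- function(dmat) {
  D <- if (inherits(dmat, "k2p_dist")) dmat$d else as.matrix(dmat)
  dropped <- character(0)
  repeat {
    bad <- !is.finite(D)
    diag(bad) <- FALSE
    if (!any(bad)) break
    counts <- rowSums(bad)
    worst <- which.max(counts)
    dropped <- c(dropped, rownames(D)[worst])
    D <- D[-worst, -worst, drop = FALSE]
  }
  list(d = D, dropped = dropped)
}

#' Write a tree as Newick
#'
#' Serializes a `phylo` tree with branch lengths at full precision;
#' labels containing spaces or Newick metacharacters are single-quoted,
#' so the output round-trips through a Newick re-parse unchanged.
#'
#' @param tree a `phylo` object with tip labels (and optionally branch
#'   lengths).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  writeLines(newick_string(tree), path)
  invisible(path)
}

newick_string <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  has_len <- !is.null(tree$edge.length)
  recurse <- function(node) {
    if (node <= n_tip) return(quote_newick_label(tree$tip.label[node]))
    kid_edges <- children[[as.character(node)]]
    parts <- vapply(kid_edges, function(e) {
      child <- tree$edge[e, 2L]
      s <- recurse(child)
      if (has_len) paste0(s, ":", format_brlen(tree$edge.length[e])) else s
    }, character(1L))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(recurse(root), ";")
}
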