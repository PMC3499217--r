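# Neighbour-joining and locus-bootstrap support.

as_dist_matrix <- function(x) {
  if (inherits(x, "pairwise_stat_matrix")) x <- x$values
  if (inherits(x, "dist")) x <- as.matrix(x)
  x <- as.matrix(x)
  if (!isSymmetric(unname(x)) || any(!is.finite(x)))
    stop_val("distance matrix must be symmetric and finite")
  x
}

#' Unrooted neighbour-joining tree
#'
#' Saitou-Nei neighbour joining with a documented deterministic tie-break
#' (the Q-criterion minimum with the lowest index pair wins) and negative
#' branch lengths clamped to zero at output (total clamped deficit recorded
#' as attribute `clamped`).  Exact on additive matrices.
#'
#' @param x a [reynolds_matrix()]/[fst_matrix()] result, a symmetric numeric
#'   matrix, or a `dist` (>= 3 taxa).
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(x) {
  d <- as_dist_matrix(x)
  n <- nrow(d)
  if (n < 3L) stop_val("neighbour joining needs >= 3 taxa")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  clamped <- 0
  fmt <- function(v) {
    if (v < 0) clamped <<- clamped + abs(v)
    sprintf("%.10g", max(v, 0))
  }
  node <- labels  # newick fragment per active cluster
  active <- seq_len(n)
  D <- d
  while (length(active) > 3L) {
    r <- length(active)
    Dr <- D[active, active]
    R <- rowSums(Dr)
    Q <- (r - 2) * Dr - outer(R, R, `+`)
    diag(Q) <- Inf
    # lowest-index pair among minima: scan column-major upper triangle
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    k <- which(Q == min(Q), arr.ind = TRUE)
    k <- k[order(k[, 1L], k[, 2L]), , drop = FALSE][1L, ]
    i <- k[1L]; j <- k[2L]
    vi <- Dr[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- Dr[i, j] - vi
    ai <- active[i]; aj <- active[j]
    merged <- paste0("(", node[ai], ":", fmt(vi), ",", node[aj], ":",
                     fmt(vj), ")")
    newd <- (D[ai, active] + D[aj, active] - D[ai, aj]) / 2
    D[ai, active] <- newd
    D[active, ai] <- newd
    D[ai, ai] <- 0
    node[ai] <- merged
    active <- active[-j]
  }
  a <- active[1L]; b <- active[2L]; c_ <- active[3L]
  va <- (D[a, b] + D[a, c_] - D[b, c_]) / 2
  vb <- (D[a, b] + D[b, c_] - D[a, c_]) / 2
  vc <- (D[a, c_] + D[b, c_] - D[a, b]) / 2
  nwk <- paste0("(", node[a], ":", fmt(va), ",", node[b], ":", fmt(vb), ",",
                node[c_], ":", fmt(vc), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

# Non-trivial bipartitions of an unrooted tree as canonical keys: the tip
# side not containing the first label alphabetically, sorted and collapsed.
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1L]
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  keys <- character(0)
  for (p in parts) {
    side <- labs[p]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2L && length(side) <= length(tips) - 2L)
      keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

# Bipartition key subtended by each internal edge (parallel to tree$edge).
edge_bipartition_keys <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1L]
  n_tip <- length(tree$tip.label)
  keys <- rep(NA_character_, nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    if (child <= n_tip) next
    side <- ape::extract.clade(tree, child)$tip.label
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2L && length(side) <= n_tip - 2L)
      keys[e] <- paste(sort(side), collapse = "|")
  }
  keys
}

#' Locus-bootstrap support for the breed tree
#'
#' Builds the full-data Reynolds-distance NJ tree, then resamples panel loci
#' with replacement `n_reps` times, recomputes the distance matrix and tree,
#' and scores each internal branch of the full-data tree by the percentage
#' of replicate trees containing the same bipartition.  Loci, the only
#' exchangeable unit here, are resampled -- not individuals.
#'
#' @param data a [genotype_dataset()].
#' @param panel optional panel restriction.
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return the full-data `ape::phylo` tree with per-internal-node support
#'   percentages in `node.label` and a `support` data.frame attribute
#'   (`bipartition`, `support_pct`).
#' @export
bootstrap_support <- function(data, panel = NULL, n_reps = 1000L, seed = 1L) {
  if (n_reps < 1L) stop_val("n_reps must be >= 1")
  ids <- resolve_panel(data, panel)
  bc <- breed_counts(data, ids)
  fr <- bc$freq
  brd <- rownames(fr)
  if (length(brd) < 3L) stop_val("bootstrap tree needs >= 3 breeds")
  # per-pair, per-locus Reynolds numerator and denominator
  pairs <- utils::combn(length(brd), 2L)
  P <- ncol(pairs); L <- length(ids)
  num <- matrix(0, P, L); den <- matrix(0, P, L)
  usable <- rep(TRUE, L)
  for (k in seq_len(P)) {
    p1 <- fr[pairs[1L, k], ]; p2 <- fr[pairs[2L, k], ]
    num[k, ] <- (p1 - p2)^2
    den[k, ] <- 1 - (p1 * p2 + (1 - p1) * (1 - p2))
    usable <- usable & !is.na(p1) & !is.na(p2)
  }
  if (!all(usable)) {
    num <- num[, usable, drop = FALSE]
    den <- den[, usable, drop = FALSE]
    L <- sum(usable)
  }
  to_matrix <- function(vals) {
    m <- matrix(0, length(brd), length(brd), dimnames = list(brd, brd))
    m[t(pairs)] <- vals
    m[t(pairs)[, 2:1, drop = FALSE]] <- vals
    m
  }
  full_tree <- nj_tree(to_matrix(rowSums(num) / rowSums(den)))
  full_keys <- edge_bipartition_keys(full_tree)
  hit <- setNames(numeric(sum(!is.na(full_keys))),
                  full_keys[!is.na(full_keys)])
  withr::with_seed(derive_seed(seed, "bootstrap"), {
    for (rep_i in seq_len(n_reps)) {
      w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
      dmat <- to_matrix(as.vector(num %*% w) / as.vector(den %*% w))
      keys <- tree_bipartitions(nj_tree(dmat))
      seen <- intersect(keys, names(hit))
      hit[seen] <- hit[seen] + 1
    }
  })
  support <- 100 * hit / n_reps
  # attach supports as node labels (ape convention)
  n_tip <- length(full_tree$tip.label)
  node_lab <- rep("", full_tree$Nnode)
  for (e in seq_len(nrow(full_tree$edge))) {
    key <- full_keys[e]
    if (!is.na(key))
      node_lab[full_tree$edge[e, 2L] - n_tip] <-
        sprintf("%.0f", support[[key]])
  }
  full_tree$node.label <- node_lab
  attr(full_tree, "support") <- data.frame(bipartition = names(support),
                                           support_pct = unname(support),
                                           stringsAsFactors = FALSE)
  full_tree
}
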