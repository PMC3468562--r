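#' Neighbor-joining tree from a distance matrix
#'
#' Classical neighbor-joining (Saitou & Nei): at each step the pair (i,j)
#' minimizing \eqn{Q(i,j) = (n-2) d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)}
#' is joined; ties in Q are broken by the smallest (row, column) index
#' pair. Branch lengths to the new node use the standard divergence
#' formula and remaining distances the standard update
#' \eqn{d(u,k) = (d(i,k)+d(j,k)-d(i,j))/2}. Negative branch lengths are
#' clamped to zero with the deficit transferred to the sister branch, so
#' the path length between the joined pair is preserved whenever the
#' sister remains nonnegative.
#'
#' On an additive matrix the returned tree reproduces the generating
#' topology and its path-length matrix equals the input.
#'
#' @param m a [barcode_dist] or square symmetric numeric matrix with
#'   dimnames; must contain no undefined (NA) entries
#' @return an unrooted `ape` \code{phylo} tree with branch lengths
#' @export
neighbor_joining <- function(m) {
  D <- as.matrix(m)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (anyNA(D)) {
    bad <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
    stop("undefined distances for pairs: ",
         paste(sprintf("(%s,%s)", rownames(D)[bad[, 1L]],
                       colnames(D)[bad[, 2L]])[seq_len(min(5L, nrow(bad)))],
               collapse = " "))
  }
  labels <- rownames(D)
  ntip <- n
  # node ids: tips 1..n; internal nodes numbered ntip+1.. as created (the
  # last-created node is the unrooted "center" and is renumbered ntip+1 for
  # the phylo convention at the end)
  node_id <- seq_len(ntip)
  next_internal <- ntip + 1L
  edge <- matrix(0L, 0L, 2L); elen <- numeric(0)
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    u <- next_internal; next_internal <- next_internal + 1L
    edge <- rbind(edge, c(u, node_id[i]), c(u, node_id[j]))
    elen <- c(elen, li, lj)
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    node_id <- c(node_id[keep], u)
    n <- n - 1L
  }
  # final 3-taxon star: closed-form lengths
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  center <- next_internal
  edge <- rbind(edge, c(center, node_id[1L]), c(center, node_id[2L]),
                c(center, node_id[3L]))
  elen <- c(elen, pmax(c(la, lb, lc), 0))
  # renumber internals so the center is ntip+1 (phylo root convention)
  internals <- (ntip + 1L):center
  newnum <- integer(center)
  newnum[seq_len(ntip)] <- seq_len(ntip)
  newnum[center] <- ntip + 1L
  others <- setdiff(internals, center)
  newnum[others] <- ntip + 1L + seq_along(others)
  edge[] <- newnum[edge]
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = labels, Nnode = ntip - 2L),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

# Canonical keys for the nontrivial leaf bipartitions of an unrooted tree.
# Each internal edge splits the leaves in two; the key is the sorted side
# not containing the alphabetically first label. Named by the child node of
# the corresponding edge.
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1L]
  desc <- descendant_tips(tree)
  child <- tree$edge[, 2L]
  internal_children <- child[child > ntip]
  keys <- vapply(internal_children, function(nd) {
    tips <- tree$tip.label[desc[[nd]]]
    if (anchor %in% tips) tips <- setdiff(tree$tip.label, tips)
    if (length(tips) < 2L || length(tips) > ntip - 2L) return(NA_character_)
    paste(sort(tips), collapse = "\r")
  }, "")
  names(keys) <- internal_children
  keys[!is.na(keys)]
}

# tip indices below each node (postorder accumulation)
descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  desc <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    p <- eo[k, 1L]; ch <- eo[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

split_key <- function(tips, all_labels) {
  anchor <- sort(all_labels)[1L]
  if (anchor %in% tips) tips <- setdiff(all_labels, tips)
  paste(sort(tips), collapse = "\r")
}

#' NJ tree with column-resampling bootstrap supports
#'
#' Builds the NJ tree of the full alignment's distance matrix, then
#' resamples alignment columns with replacement B times (same length),
#' rebuilds the tree on each replicate, and annotates each internal edge of
#' the full-data tree with the percentage of replicates whose tree contains
#' the same leaf bipartition. Replicates whose distance matrix contains
#' saturated (undefined) entries are dropped and counted; a warning is
#' raised when more than 10% are dropped. Replicate r draws its resampling
#' from a substream deterministically derived from (seed, r), so results
#' are reproducible and independent of leaf input order.
#'
#' @param aln a [barcode_alignment]
#' @param kind distance kind used for the matrices
#' @param B number of bootstrap replicates (>= 1)
#' @param seed integer RNG seed governing all replicates
#' @param deletion column-deletion mode
#' @param block resampling-unit width in columns: 1 = single columns
#'   (default), 3 = whole codons
#' @return the full-data \code{phylo} tree with `node.label` holding
#'   integer percentage supports ("" at the root); attribute `n_dropped`
#'   counts discarded replicates
#' @export
bootstrap_tree <- function(aln, kind = "k2p_total", B = 100L, seed = 1L,
                           deletion = c("pairwise", "complete"), block = 1L) {
  deletion <- match.arg(deletion)
  stopifnot(B >= 1L)
  full <- pairwise_matrix(aln, kind, deletion)
  tree <- neighbor_joining(full)
  keys <- tree_bipartitions(tree)
  counts <- setNames(numeric(length(keys)), names(keys))
  L <- aln_length(aln)
  nblock <- L %/% block
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, B)
  n_dropped <- 0L
  for (r in seq_len(B)) {
    set.seed(rep_seeds[r])
    bs <- sample.int(nblock, nblock, replace = TRUE)
    cols <- if (block == 1L) bs
            else as.vector(outer(seq_len(block) - 1L, (bs - 1L) * block + 1L,
                                 `+`))
    rep_aln <- aln
    rep_aln$mat <- aln$mat[, cols, drop = FALSE]
    mb <- tryCatch(pairwise_matrix(rep_aln, kind, deletion),
                   error = function(e) NULL)
    if (is.null(mb) || anyNA(as.matrix(mb))) {
      n_dropped <- n_dropped + 1L
      next
    }
    bt <- neighbor_joining(mb)
    bkeys <- tree_bipartitions(bt)
    hit <- keys %in% bkeys
    counts[hit] <- counts[hit] + 1
  }
  kept <- B - n_dropped
  if (n_dropped > 0.1 * B)
    warning(n_dropped, " of ", B, " bootstrap replicates dropped ",
            "(saturated distances)")
  if (kept == 0L) stop("all bootstrap replicates dropped")
  support <- round(100 * counts / kept)
  ntip <- length(tree$tip.label)
  node.label <- character(tree$Nnode)
  node.label[as.integer(names(keys)) - ntip] <- as.character(support)
  tree$node.label <- node.label
  attr(tree, "n_dropped") <- n_dropped
  tree
}

#' Test species monophyly on a tree
#'
#' A species with two or more leaves is monophyletic iff some edge of the
#' (unrooted) tree separates exactly its leaves from all others; singleton
#' species are reported trivially monophyletic. When the tree carries
#' bootstrap node labels, the support of the species-defining edge is
#' reported.
#'
#' @param tree a \code{phylo} whose tip labels are seq_ids
#' @param grouping named character vector seq_id -> species covering all
#'   leaves
#' @return data frame with columns `species`, `n_leaves`, `monophyletic`,
#'   `support`
#' @export
species_monophyly <- function(tree, grouping) {
  if (!all(tree$tip.label %in% names(grouping)))
    stop("grouping does not cover all leaves")
  keys <- tree_bipartitions(tree)
  sup <- rep(NA_real_, length(keys))
  if (!is.null(tree$node.label)) {
    ntip <- length(tree$tip.label)
    lab <- tree$node.label[as.integer(names(keys)) - ntip]
    sup <- suppressWarnings(as.numeric(lab))
  }
  species <- unname(grouping[tree$tip.label])
  out <- lapply(sort(unique(species)), function(sp) {
    tips <- tree$tip.label[species == sp]
    if (length(tips) < 2L)
      return(data.frame(species = sp, n_leaves = 1L, monophyletic = TRUE,
                        support = NA_real_, stringsAsFactors = FALSE))
    key <- split_key(tips, tree$tip.label)
    hit <- which(keys == key)
    data.frame(species = sp, n_leaves = length(tips),
               monophyletic = length(hit) > 0L,
               support = if (length(hit)) sup[hit[1L]] else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Path-length (patristic) distance matrix of a tree
#'
#' @param tree a \code{phylo}
#' @return symmetric matrix of leaf-to-leaf path lengths, ordered and
#'   labeled by tip label
#' @export
tree_path_lengths <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}
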