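# Small fixtures built in code.

# alignment from a named character vector of strings
make_aln <- function(seqs, species = NULL, frame_offset = 0) {
  meta <- NULL
  if (!is.null(species))
    meta <- data.frame(seq_id = names(seqs), species = species,
                       stringsAsFactors = FALSE)
  barcode_alignment(seqs, meta, frame_offset = frame_offset)
}

# random aligned pair of given length over ACGT with optional gap/N noise
random_pair <- function(L, gap_frac = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw <- function() {
    x <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    if (gap_frac > 0) {
      k <- rbinom(1, L, gap_frac)
      x[sample.int(L, k)] <- sample(c("-", "N"), k, replace = TRUE)
    }
    paste(x, collapse = "")
  }
  c(a = draw(), b = draw())
}

# naive per-column reference implementation of pair counting
naive_count <- function(a, b) {
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  bases <- c("A", "C", "G", "T")
  L <- n_ts <- n_tv <- 0L
  for (i in seq_along(va)) {
    if (!(va[i] %in% bases) || !(vb[i] %in% bases)) next
    L <- L + 1L
    if (va[i] == vb[i]) next
    pur <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
    if (pur[va[i]] == pur[vb[i]]) n_ts <- n_ts + 1L else n_tv <- n_tv + 1L
  }
  list(L = L, n_ts = n_ts, n_tv = n_tv)
}

# random unrooted binary tree with additive patristic matrix
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.05, 1))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# canonical bipartition set of an unrooted tree (for topology comparison)
biparts <- function(tree) sort(unname(barcodegap:::tree_bipartitions(tree)))

split_key_of <- function(tips, all_labels)
  barcodegap:::split_key(tips, all_labels)

drop_rows <- function(aln, ids) {
  keep <- !rownames(aln$mat) %in% ids
  aln$mat <- aln$mat[keep, , drop = FALSE]
  aln$meta <- aln$meta[keep, , drop = FALSE]
  aln
}

expect_same_topology <- function(t1, t2) {
  expect_identical(biparts(t1), biparts(t2))
}
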