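test_that("NJ reconstructs the 4-taxon additive example exactly", {
  labs <- c("A", "B", "C", "D")
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, dimnames = list(labs, labs))
  tr <- neighbor_joining(D)
  # AB|CD split present
  expect_true(paste(sort(c("C", "D")), collapse = "\r") %in% biparts(tr) ||
              paste(sort(c("B", "A")), collapse = "\r") %in% biparts(tr))
  # terminal branch lengths 1,2,3,4 and internal branch 1
  tip_len <- setNames(tr$edge.length[match(1:4, tr$edge[, 2])],
                      tr$tip.label)
  expect_equal(tip_len[labs], c(A = 1, B = 2, C = 3, D = 4))
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(sort(internal), 1)
  # path lengths reproduce the input matrix
  expect_equal(tree_path_lengths(tr)[labs, labs], D, tolerance = 1e-9)
})

test_that("3 taxa give the unique star with closed-form lengths", {
  D <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  expect_equal(tr$Nnode, 1L)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(len[c("a", "b", "c")],
               c(a = (0.3 + 0.5 - 0.6) / 2, b = (0.3 + 0.6 - 0.5) / 2,
                 c = (0.5 + 0.6 - 0.3) / 2))
})

test_that("NJ is exact on random additive matrices (topology and path
           lengths)", {
  for (s in 1:20) {
    n <- sample(4:8, 1)
    ra <- random_additive(n, seed = 100 + s)
    tr <- neighbor_joining(ra$D)
    expect_same_topology(tr, ra$tree)
    expect_equal(tree_path_lengths(tr)[rownames(ra$D), colnames(ra$D)],
                 ra$D, tolerance = 1e-9)
  }
})

test_that("two tight clusters are separated by one internal edge", {
  labs <- paste0("t", 1:6)
  D <- matrix(0.2, 6, 6, dimnames = list(labs, labs))
  within <- as.matrix(expand.grid(1:3, 1:3))
  D[within] <- 0.01
  D[within + 3L] <- 0.01
  diag(D) <- 0
  tr <- neighbor_joining(D)
  expect_true(split_key_of(labs[1:3], labs) %in% biparts(tr))
})

test_that("undefined entries and tiny inputs are rejected", {
  labs <- c("a", "b", "c")
  D <- matrix(c(0, NA, .2, NA, 0, .3, .2, .3, 0), 3,
              dimnames = list(labs, labs))
  expect_error(neighbor_joining(D), "undefined.*\\(a,b\\)")
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("Q ties break deterministically and output is reproducible", {
  labs <- paste0("t", 1:4)
  D <- matrix(0.1, 4, 4, dimnames = list(labs, labs))  # fully tied
  diag(D) <- 0
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  # smallest (row, column) pair joined first: t1,t2 form a cherry
  expect_true(split_key_of(c("t1", "t2"), labs) %in% biparts(t1))
})

test_that("negative branch lengths are clamped with the deficit
           transferred", {
  labs <- c("a", "b", "c", "d")
  # non-additive matrix known to produce a negative NJ branch
  D <- matrix(c(0, .1, .4, .45,
                .1, 0, .42, .47,
                .4, .42, 0, .05,
                .45, .47, .05, 0), 4, dimnames = list(labs, labs))
  tr <- neighbor_joining(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports behave at the extremes", {
  sim <- simulate_community(sim_config(n_genera = 2, species_per_genus = 2,
                                       individuals_per_species = 2,
                                       seq_length = 400, seed = 9))
  aln <- sim$alignment
  # B = 1: every support is 0 or 100
  tr <- bootstrap_tree(aln, B = 1, seed = 4)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
  # two identical copies, well separated from everything else, form a
  # cherry supported in every replicate (their distance is invariantly 0)
  dup <- aln$mat[1, ]
  mut <- seq(10, 200, by = 10)
  dup[mut] <- vapply(dup[mut], function(b)
    c(A = "C", C = "A", G = "T", T = "G", "-" = "A", N = "A")[[b]], "")
  aln2 <- aln
  aln2$mat <- rbind(aln$mat, dup1 = dup, dup2 = dup)
  aln2$meta <- rbind(aln$meta,
                     data.frame(seq_id = c("dup1", "dup2"),
                                species = "Genus09 dup",
                                genus = "Genus09",
                                site = "", accession = ""))
  tr2 <- bootstrap_tree(aln2, B = 20, seed = 4)
  keys <- barcodegap:::tree_bipartitions(tr2)
  cherry <- split_key_of(c("dup1", "dup2"), rownames(aln2$mat))
  hit <- which(keys == cherry)
  expect_length(hit, 1L)
  ntip <- length(tr2$tip.label)
  expect_equal(tr2$node.label[as.integer(names(keys)[hit]) - ntip], "100")
})

test_that("bootstrap supports are reproducible and leaf-order invariant", {
  sim <- simulate_community(sim_config(n_genera = 2, species_per_genus = 3,
                                       individuals_per_species = 2,
                                       seq_length = 300, seed = 21))
  aln <- sim$alignment
  support_map <- function(a) {
    tr <- bootstrap_tree(a, B = 30, seed = 77)
    keys <- barcodegap:::tree_bipartitions(tr)
    ntip <- length(tr$tip.label)
    setNames(tr$node.label[as.integer(names(keys)) - ntip], unname(keys))
  }
  s1 <- support_map(aln)
  perm <- rev(seq_len(n_seq(aln)))
  aln_r <- aln
  aln_r$mat <- aln$mat[perm, , drop = FALSE]
  aln_r$meta <- aln$meta[perm, , drop = FALSE]
  s2 <- support_map(aln_r)
  shared <- intersect(names(s1), names(s2))
  expect_equal(sort(names(s1)), sort(names(s2)))
  expect_identical(s1[shared], s2[shared])
})

test_that("species monophyly is detected from tree bipartitions", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  grp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  mono <- species_monophyly(ape::unroot(tr), grp)
  expect_true(all(mono$monophyletic))
  tr2 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  mono2 <- species_monophyly(ape::unroot(tr2), grp)
  expect_false(any(mono2$monophyletic))
  # singleton species are trivially monophyletic
  grp3 <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "C")
  mono3 <- species_monophyly(ape::unroot(tr), grp3)
  expect_true(mono3$monophyletic[mono3$species == "C"])
  expect_equal(mono3$n_leaves[mono3$species == "C"], 1L)
})

test_that("a clean simulated community is fully monophyletic with an
           independent NJ cross-check", {
  sim <- simulate_community(sim_config(seed = 13))
  m <- pairwise_matrix(sim$alignment)
  tr <- neighbor_joining(m)
  grp <- setNames(sim$truth$sequences$species, sim$truth$sequences$seq_id)
  expect_true(all(species_monophyly(tr, grp)$monophyletic))
  # ape's NJ on the same matrix finds the same species clusters
  tra <- ape::nj(stats::as.dist(as.matrix(m)))
  expect_true(all(species_monophyly(tra, grp)$monophyletic))
})
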