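test_that("pair counting distinguishes transitions, transversions and
           excluded columns", {
  id <- count_pair("ACGT", "ACGT")
  expect_equal(unlist(id[c("L", "n_ts", "n_tv")]), c(L = 4, n_ts = 0,
                                                     n_tv = 0))
  ts <- count_pair("ACGT", "GCGT")   # A->G transition
  expect_equal(ts$n_ts, 1)
  expect_equal(ts$n_tv, 0)
  pd <- count_pair("A-GTN", "AAGTA") # pairwise deletion of cols 2 and 5
  expect_equal(pd$L, 3)
  expect_equal(pd$n_ts + pd$n_tv, 0)
  expect_error(count_pair("---", "AAA"), "no comparable sites")
  expect_error(count_pair("AC", "ACG"), "length")
})

test_that("pair counting is symmetric and matches a naive per-column loop", {
  set.seed(7)
  for (rep in 1:20) {
    p <- random_pair(300, gap_frac = 0.05)
    ab <- count_pair(p["a"], p["b"])
    ba <- count_pair(p["b"], p["a"])
    expect_identical(unclass(ab), unclass(ba))
    ref <- naive_count(p["a"], p["b"])
    expect_equal(ab$L, ref$L)
    expect_equal(ab$n_ts, ref$n_ts)
    expect_equal(ab$n_tv, ref$n_tv)
  }
})

test_that("K2P closed forms match the high-precision oracle values", {
  # frozen from a 50-digit evaluation of the closed forms
  expect_equal(k2p(0.10, 0.05), 0.17018116514034704, tolerance = 1e-14)
  expect_equal(k2p_transition(0.10, 0.05), 0.11750090731143389,
               tolerance = 1e-14)
  expect_equal(k2p_transversion(0.10, 0.05), 0.052680257828913151,
               tolerance = 1e-14)
  # with no transitions the transition component can be slightly negative;
  # the subtraction of two near-equal logs limits attainable precision
  expect_equal(k2p_transition(0, 0.05), -0.00069348172068130859,
               tolerance = 1e-9)
  expect_identical(k2p(0, 0), 0)
  expect_identical(k2p_transversion(0.1, 0), 0)
})

test_that("saturation yields an undefined flag, not an error", {
  expect_true(is.na(k2p(0.5, 0.25)))       # 1-2P-Q = -0.25
  expect_true(is.na(k2p(0.1, 0.5)))        # 1-2Q = 0
  expect_true(is.na(k2p_transition(0.5, 0.25)))
  expect_true(is.na(k2p_transversion(0.2, 0.5)))
})

test_that("transition and transversion components add to the total", {
  set.seed(11)
  n <- 0
  while (n < 1000) {
    P <- runif(1, 0, 0.45); Q <- runif(1, 0, 0.45)
    if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) next
    n <- n + 1
    expect_equal(k2p_transition(P, Q) + k2p_transversion(P, Q), k2p(P, Q),
                 tolerance = 1e-12)
  }
})

test_that("K2P is monotone in P and Q and approaches p-distance at the
           origin", {
  for (Q in c(0, 0.05, 0.1)) {
    d <- vapply(seq(0, 0.4, by = 0.01), function(P) k2p(P, Q), 0)
    expect_true(all(diff(d) > 0))
  }
  for (P in c(0, 0.05, 0.1)) {
    d <- vapply(seq(0, 0.35, by = 0.01), function(Q) k2p(P, Q), 0)
    expect_true(all(diff(d) > 0))
  }
  # small-divergence limit: k2p / p -> 1
  P <- 6e-5; Q <- 4e-5
  expect_equal(k2p(P, Q) / (P + Q), 1, tolerance = 1e-3)
})

test_that("R-value is the mean per-pair count ratio with zero-transversion
           pairs excluded", {
  mk <- function(ts, tv) structure(list(L = 100, n_ts = ts, n_tv = tv,
                                        P = ts / 100, Q = tv / 100),
                                   class = "pair_counts")
  expect_equal(as.numeric(r_value(list(mk(10, 5)))), 2.0)
  expect_equal(as.numeric(r_value(list(mk(2, 1), mk(1, 1)))), 1.5)
  r <- r_value(list(mk(2, 1), mk(3, 0)))
  expect_equal(as.numeric(r), 2.0)
  expect_equal(attr(r, "n_excluded"), 1L)
  expect_warning(r0 <- r_value(list(mk(1, 0))), "undefined")
  expect_true(is.na(r0))
})

test_that("pairwise matrices agree with per-pair computation and with an
           independent K80 implementation", {
  aln <- make_aln(c(x = "AAGCTTAGGCAT", y = "AAACTTAGACAT",
                    z = "TAGCTAAGGCCT"))
  m <- pairwise_matrix(aln, "k2p_total")
  v <- as.matrix(m)
  for (pair in list(c("x", "y"), c("x", "z"), c("y", "z"))) {
    pc <- count_pair(paste(aln$mat[pair[1], ], collapse = ""),
                     paste(aln$mat[pair[2], ], collapse = ""))
    expect_equal(v[pair[1], pair[2]], k2p(pc), tolerance = 1e-14)
  }
  expect_equal(diag(v), c(x = 0, y = 0, z = 0))
  # p-distance kind equals (n_ts + n_tv)/L
  mp <- as.matrix(pairwise_matrix(aln, "p_distance"))
  pc <- count_pair("AAGCTTAGGCAT", "AAACTTAGACAT")
  expect_equal(mp["x", "y"], (pc$n_ts + pc$n_tv) / pc$L)
  # identical records give off-diagonal zero
  m0 <- as.matrix(pairwise_matrix(make_aln(c(a = "ACGT", b = "ACGT"))))
  expect_equal(m0["a", "b"], 0)
  # cross-check vs ape::dist.dna on a gappy simulated alignment
  sim <- simulate_community(sim_config(n_genera = 2, species_per_genus = 2,
                                       individuals_per_species = 3,
                                       seq_length = 300, seed = 5))
  aln2 <- sim$alignment
  aln2$mat[1, 5:10] <- "-"; aln2$mat[3, 50] <- "N"
  ours <- as.matrix(pairwise_matrix(aln2, "k2p_total"))
  theirs <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(aln2$mat)),
                                    model = "K80",
                                    pairwise.deletion = TRUE))
  expect_equal(ours, theirs[rownames(ours), colnames(ours)],
               tolerance = 1e-12)
})

test_that("complete deletion drops every gapped or ambiguous column
           globally", {
  aln <- make_aln(c(a = "ACGTAC", b = "A-GTAC", c = "ACGTNC"))
  cc <- pair_counts_matrix(aln, deletion = "complete")
  expect_true(all(cc$L[upper.tri(cc$L)] == 4))
  cp <- pair_counts_matrix(aln, deletion = "pairwise")
  expect_equal(cp$L["a", "c"], 5L)
})

test_that("group summaries partition pairs into the three divergence
           categories", {
  # two singleton species: conspecific pool empty, between mean = 0.08
  v <- matrix(c(0, 0.08, 0.08, 0), 2,
              dimnames = list(c("s1", "s2"), c("s1", "s2")))
  gs <- group_summary(barcode_dist(v), c(s1 = "Aedes a", s2 = "Aedes b"))
  expect_equal(length(gs$pools$conspecific), 0L)
  expect_equal(gs$pools$congeneric, 0.08)
  expect_true(is.na(gs$per_taxon$mean_within[1]))
  expect_equal(gs$per_pair$mean_between, 0.08)
  # 3-category pooling with intergeneric pair
  aln <- make_aln(c(a1 = "ACGTACGTAC", a2 = "ACGTACGTAC",
                    b1 = "ACGAACGTAC", c1 = "ACGTACGTCC"),
                  species = c("Aedes x", "Aedes x", "Aedes y", "Culex z"))
  m <- pairwise_matrix(aln)
  gs2 <- group_summary(m, setNames(aln$meta$species, aln$meta$seq_id))
  expect_equal(length(gs2$pools$conspecific), 1L)
  expect_equal(length(gs2$pools$congeneric), 2L)
  expect_equal(length(gs2$pools$intergeneric), 3L)
  npairs <- choose(4, 2)
  expect_equal(sum(lengths(gs2$pools)) + gs2$n_undefined, npairs)
})

test_that("grouped pool ranges match the simulator's programmed depths", {
  sim <- simulate_community(sim_config(seed = 3))
  m <- pairwise_matrix(sim$alignment)
  grp <- setNames(sim$truth$sequences$species, sim$truth$sequences$seq_id)
  gs <- group_summary(m, grp)
  expect_equal(mean(gs$pools$conspecific), sim$truth$depths[["conspecific"]],
               tolerance = 0.35)
  expect_equal(mean(gs$pools$congeneric), sim$truth$depths[["congeneric"]],
               tolerance = 0.12)
  expect_true(max(gs$pools$conspecific) < min(gs$pools$congeneric))
  expect_true(max(gs$pools$congeneric) < min(gs$pools$intergeneric))
})

test_that("K2P estimates recover the true simulated distance", {
  for (d_true in c(0.01, 0.05, 0.15)) {
    est <- vapply(1:200, function(r) {
      pair <- simulate_pair(d_true, kappa = 1.4, length = 650,
                            seed = 1000 * d_true + r)
      k2p(count_pair(pair$mat[1, ], pair$mat[2, ]))
    }, 0)
    se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - d_true), 3 * se + 1e-12)
  }
})
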