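mk_dist <- function(v, labs, kind = "k2p_total") {
  dimnames(v) <- list(labs, labs)
  barcode_dist(v, kind)
}

test_that("gap summary pools and ratio on a constructed community", {
  labs <- c("a1", "a2", "b1", "b2")
  grp <- c(a1 = "Aedes a", a2 = "Aedes a", b1 = "Aedes b", b2 = "Aedes b")
  v <- matrix(0.08, 4, 4); diag(v) <- 0
  v[1, 2] <- v[2, 1] <- 0.005; v[3, 4] <- v[4, 3] <- 0.005
  mt <- mk_dist(v, labs)
  mv <- mk_dist(v / 10, labs, "k2p_transversion")
  gs <- gap_summary(mt, mv, grp)
  expect_equal(sort(gs$pools$k2p_total$conspecific), c(0.005, 0.005))
  expect_equal(gs$pools$k2p_total$congeneric, rep(0.08, 4))
  expect_equal(gs$ratio_congeneric_over_conspecific, 16)
  expect_equal(gs$pct_conspecific_below_theta, 100)
  expect_equal(gs$pct_congeneric_above_theta, 100)
  # pools exhaust all defined pairs
  expect_equal(sum(lengths(gs$pools$k2p_total)), choose(4, 2))
})

test_that("all-singleton communities have an undefined ratio", {
  labs <- c("s1", "s2")
  grp <- c(s1 = "Aedes a", s2 = "Aedes b")
  v <- matrix(c(0, .08, .08, 0), 2)
  gs <- gap_summary(mk_dist(v, labs), mk_dist(v / 8, labs,
                                              "k2p_transversion"), grp)
  expect_equal(length(gs$pools$k2p_total$conspecific), 0L)
  expect_true(is.na(gs$ratio_congeneric_over_conspecific))
})

test_that("taxon exclusions are removed before pooling", {
  labs <- c("a1", "a2", "m1", "m2")
  grp <- c(a1 = "Aedes a", a2 = "Aedes a",
           m1 = "Culex mimulus", m2 = "Culex mimulus")
  v <- matrix(0.1, 4, 4); diag(v) <- 0
  v[1, 2] <- v[2, 1] <- 0.004
  v[3, 4] <- v[4, 3] <- 0.05          # anomalously deep conspecific pair
  gs <- gap_summary(mk_dist(v, labs), mk_dist(v / 8, labs,
                                              "k2p_transversion"), grp,
                    exclusions = "Culex mimulus")
  expect_equal(gs$pools$k2p_total$conspecific, 0.004)
  expect_equal(gs$excluded, "Culex mimulus")
})

test_that("queries are assigned by nearest reference under the K2P
           threshold", {
  refs <- make_aln(c(r1 = "ACGTACGTACGTACGTACGT", r2 = "ACGTACGTACGTACGTACGA",
                     r3 = "TGCATGCAGGCATCCATGCA"),
                   species = c("Aedes a", "Aedes a", "Culex b"))
  # identical to r1 -> assigned with d = 0
  a <- classify_query("ACGTACGTACGTACGTACGT", refs)
  expect_equal(a$assignment, "Aedes a")
  expect_equal(a$distance, 0)
  expect_equal(a$top3$seq_id[1], "r1")
  # far from everything -> unassigned
  b <- classify_query("GGGGGGGGGGCCCCCCCCCC", refs)
  expect_equal(b$assignment, "unassigned")
  # equidistant between two species -> ambiguous with both reported
  refs2 <- make_aln(c(r1 = "AAAAAAAAAA", r2 = "CCAAAAAAAA"),
                    species = c("Aedes a", "Culex b"))
  cl <- classify_query("ACAAAAAAAA", refs2, barcode_thresholds(0.9, 0.5))
  expect_equal(cl$assignment, "ambiguous")
  expect_equal(cl$tied_species, c("Aedes a", "Culex b"))
})

test_that("classification is reference-order invariant and monotone in the
           threshold", {
  sim <- simulate_community(sim_config(n_genera = 2, species_per_genus = 2,
                                       individuals_per_species = 3,
                                       seq_length = 400, seed = 19))
  refs <- sim$alignment
  q <- paste(refs$mat[1, ], collapse = "")
  refs1 <- refs
  perm <- rev(seq_len(n_seq(refs)))
  refs1$mat <- refs$mat[perm, , drop = FALSE]
  refs1$meta <- refs$meta[perm, , drop = FALSE]
  a1 <- classify_query(q, refs)
  a2 <- classify_query(q, refs1)
  expect_equal(a1$assignment, a2$assignment)
  expect_equal(a1$distance, a2$distance)
  # lowering theta never turns unassigned into assigned
  for (th in c(0.05, 0.02, 0.008, 0.002)) {
    res <- classify_query(q, refs, barcode_thresholds(th, th / 2))
    if (res$assignment == "unassigned") unassigned_seen <- TRUE
    if (exists("unassigned_seen") && isTRUE(unassigned_seen))
      expect_equal(res$assignment, "unassigned")
  }
})

test_that("cryptic and synonymy candidates are flagged at the thresholds", {
  labs <- c("d1", "d2", "s1", "s2", "m1", "p1")
  grp <- c(d1 = "Aedes dorsalis", d2 = "Aedes dorsalis",
           s1 = "Anopheles sinensis", s2 = "Anopheles sinensis",
           m1 = "Culex minor", p1 = "Culex spiculosus")
  vt <- matrix(0.12, 6, 6); diag(vt) <- 0
  vt[1, 2] <- vt[2, 1] <- 0.0298   # deep within-species split
  vt[3, 4] <- vt[4, 3] <- 0.0261   # deep but transversion-quiet
  vt[5, 6] <- vt[6, 5] <- 0.0186   # shallow between-species pair
  vv <- matrix(0.05, 6, 6); diag(vv) <- 0
  vv[1, 2] <- vv[2, 1] <- 0.0111
  vv[3, 4] <- vv[4, 3] <- 0.0018
  vv[5, 6] <- vv[6, 5] <- 0.0037
  gs <- gap_summary(mk_dist(vt, labs), mk_dist(vv, labs,
                                               "k2p_transversion"), grp)
  fl <- flag_taxa(gs)
  expect_setequal(fl$cryptic$species,
                  c("Aedes dorsalis", "Anopheles sinensis"))
  expect_true(fl$cryptic$strong[fl$cryptic$species == "Aedes dorsalis"])
  expect_false(fl$cryptic$strong[fl$cryptic$species ==
                                 "Anopheles sinensis"])
  expect_equal(nrow(fl$synonymy), 1L)
  expect_setequal(unlist(fl$synonymy[1, c("taxon_a", "taxon_b")]),
                  c("Culex minor", "Culex spiculosus"))
  expect_true(fl$synonymy$plesiomorphic[1])
  # a tight species is never flagged
  labs2 <- c("x1", "x2")
  gs2 <- gap_summary(mk_dist(matrix(c(0, .005, .005, 0), 2), labs2),
                     mk_dist(matrix(c(0, .001, .001, 0), 2), labs2,
                             "k2p_transversion"),
                     c(x1 = "Aedes x", x2 = "Aedes x"))
  fl2 <- flag_taxa(gs2)
  expect_equal(nrow(fl2$cryptic), 0L)
})

test_that("ts/tv curves match a brute-force group-by and locate the
           crossover", {
  sim <- simulate_community(sim_config(seed = 23, kappa = 0.5))
  counts <- pair_counts_matrix(sim$alignment)
  curve <- ts_tv_curve(counts, bins = 10)
  # independent group-by oracle
  ut <- upper.tri(counts$L)
  P <- (counts$TS / counts$L)[ut]; Q <- (counts$TV / counts$L)[ut]
  d <- mapply(k2p, P, Q); ds <- mapply(k2p_transition, P, Q)
  dv <- mapply(k2p_transversion, P, Q)
  def <- !is.na(d)
  bins <- seq(0, max(d[def]) * (1 + 1e-9), length.out = 11)
  cuts <- cut(d[def], bins, include.lowest = TRUE)
  expect_equal(curve$mean_ds,
               as.numeric(tapply(ds[def], cuts, mean)[
                 !is.na(tapply(ds[def], cuts, mean))]),
               tolerance = 1e-12)
  expect_equal(curve$mean_dv,
               as.numeric(tapply(dv[def], cuts, mean)[
                 !is.na(tapply(dv[def], cuts, mean))]),
               tolerance = 1e-12)
  # kappa < 1: transversions overtake transitions at depth
  expect_false(is.na(attr(curve, "crossover")))
  # all-transition pairs give an identically zero transversion curve
  aln0 <- make_aln(c(a = "AAAAAAAAAA", b = "GGGGGAAAAA",
                     c = "GGAAAAAAAA"))
  c0 <- ts_tv_curve(pair_counts_matrix(aln0), bins = 3)
  expect_true(all(c0$mean_dv == 0))
})
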