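# Default per-codon-position equilibrium base frequencies (rows: codon
# positions 1-3; columns A,C,G,T). Strongly A+T-rich third positions
# (~93% A+T), T-poorer/A-richer first than second positions; pooled A+T
# ~69% — the composition regime of culicid COI barcodes.
.DEFAULT_BASE_FREQS <- matrix(
  c(0.31, 0.17, 0.26, 0.26,
    0.18, 0.26, 0.17, 0.39,
    0.45, 0.045, 0.021, 0.484),
  nrow = 3, byrow = TRUE,
  dimnames = list(c("pos1", "pos2", "pos3"), c("A", "C", "G", "T")))

#' Configuration for the synthetic barcode-community generator
#'
#' Defaults target the divergence structure observed in large COI barcode
#' surveys of mosquito communities: within-species ("conspecific")
#' expected divergence 0.4%, same-genus ("congeneric") 8%, between-genus
#' ("intergeneric") 16%; transition/transversion rate ratio kappa 1.4
#' (yielding a count R-value near 0.7); relative substitution rates 5:1:18
#' across codon positions 1:2:3; and A+T-biased composition, extreme at
#' third positions. Depths are expected pairwise distances and are
#' converted internally to branch lengths of the genus/species/individual
#' hierarchy.
#'
#' @param n_genera,species_per_genus,individuals_per_species community
#'   shape (defaults 5, 4, 4)
#' @param conspecific_depth,congeneric_depth,intergeneric_depth expected
#'   pairwise distances within species / within genus between species /
#'   between genera (must be strictly increasing)
#' @param kappa transition/transversion rate ratio
#' @param position_rates relative substitution rates at codon positions
#'   1,2,3 (normalized internally to mean 1)
#' @param base_freqs 3x4 matrix of per-position A,C,G,T root frequencies
#' @param seq_length alignment length in bp
#' @param numt_rate fraction of individuals replaced by an injected
#'   pseudogene copy (0 disables)
#' @param seed integer RNG seed
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_genera = 5L, species_per_genus = 4L,
                       individuals_per_species = 4L,
                       conspecific_depth = 0.004, congeneric_depth = 0.08,
                       intergeneric_depth = 0.16, kappa = 1.4,
                       position_rates = c(5, 1, 18),
                       base_freqs = .DEFAULT_BASE_FREQS,
                       seq_length = 650L, numt_rate = 0, seed = 1L) {
  if (!(conspecific_depth < congeneric_depth &&
        congeneric_depth < intergeneric_depth))
    stop("infeasible depth ordering: conspecific < congeneric < ",
         "intergeneric required")
  stopifnot(all(position_rates > 0), kappa > 0, seq_length >= 3L,
            nrow(base_freqs) == 3L, ncol(base_freqs) == 4L,
            abs(rowSums(base_freqs) - 1) < 1e-9,
            numt_rate >= 0, numt_rate <= 1)
  structure(list(n_genera = as.integer(n_genera),
                 species_per_genus = as.integer(species_per_genus),
                 individuals_per_species = as.integer(individuals_per_species),
                 conspecific_depth = conspecific_depth,
                 congeneric_depth = congeneric_depth,
                 intergeneric_depth = intergeneric_depth,
                 kappa = kappa,
                 position_rates = position_rates / mean(position_rates),
                 base_freqs = base_freqs, seq_length = as.integer(seq_length),
                 numt_rate = numt_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# One step of the K2P (K80) substitution process, vectorized over sites.
# codes: integer parent sequence (A=1,G=2,C=3,T=4); t: expected
# substitutions per site (may vary by site); kappa: ts/tv rate ratio.
# Rates are normalized so alpha + 2*beta = 1, i.e. t is in distance units.
k2p_evolve <- function(codes, t, kappa) {
  beta <- 1 / (kappa + 2); alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  p_tv <- 0.25 - 0.25 * e1          # each of the two transversion targets
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  u <- stats::runif(length(codes))
  ts_partner <- c(2L, 1L, 4L, 3L)[codes]
  purine <- codes <= 2L
  tv_a <- ifelse(purine, 3L, 1L)
  tv_b <- ifelse(purine, 4L, 2L)
  out <- codes
  out[u < p_ts] <- ts_partner[u < p_ts]
  sel <- u >= p_ts & u < p_ts + p_tv
  out[sel] <- tv_a[sel]
  sel <- u >= p_ts + p_tv & u < p_ts + 2 * p_tv
  out[sel] <- tv_b[sel]
  out
}

# indices (first position) of full in-frame codons, frame offset 0
stop_codon_starts <- function(codes) {
  L <- length(codes)
  starts <- seq(1L, L - 2L, by = 3L)
  c1 <- codes[starts]; c2 <- codes[starts + 1L]; c3 <- codes[starts + 2L]
  # stops under the invertebrate mitochondrial code: TAA, TAG
  starts[c1 == 4L & c2 == 1L & (c3 == 1L | c3 == 2L)]
}

# Evolve one branch as the K2P jump chain conditioned on its expected
# event count: the number of substitution events is the branch's expected
# total (stochastically rounded, so expectation is exact), events land on
# sites with probability proportional to their rate multiplier, and each
# event is a transition with probability kappa/(kappa+2) or one of the two
# transversions otherwise. Conditioning on the expected count keeps
# realized lineage depths tight around the programmed values while leaving
# the per-site substitution law (and hence K2P estimator consistency)
# intact. Functional lineages revert any codon that became an in-frame
# stop back to the parent codon.
evolve_branch <- function(parent, b, mult, kappa, reject_stops = TRUE) {
  lambda <- b * sum(mult)
  k <- floor(lambda) + (stats::runif(1) < lambda %% 1)
  child <- parent
  if (k > 0) {
    sites <- sample.int(length(parent), k, replace = TRUE, prob = mult)
    p_ts <- kappa / (kappa + 2)
    for (s in sites) {
      base <- child[s]
      child[s] <- if (stats::runif(1) < p_ts) c(2L, 1L, 4L, 3L)[base]
                  else if (base <= 2L) sample(3:4, 1L) else sample(1:2, 1L)
    }
  }
  if (reject_stops) {
    bad <- stop_codon_starts(child)
    for (s in bad) child[s:(s + 2L)] <- parent[s:(s + 2L)]
  }
  child
}

# root sequence from per-position base frequencies, resampling any codon
# that forms an in-frame stop
random_root <- function(cfg) {
  L <- cfg$seq_length
  posclass <- ((seq_len(L) - 1L) %% 3L) + 1L
  codes <- integer(L)
  code_of <- c(A = 1L, C = 3L, G = 2L, T = 4L)  # freq columns are A,C,G,T
  for (p in 1:3) {
    n <- sum(posclass == p)
    codes[posclass == p] <- sample(code_of, n, replace = TRUE,
                                   prob = cfg$base_freqs[p, ])
  }
  for (iter in 1:100) {
    bad <- stop_codon_starts(codes)
    if (!length(bad)) break
    for (s in bad)
      for (k in 0:2)
        codes[s + k] <- sample(code_of, 1L,
                               prob = cfg$base_freqs[((s + k - 1L) %% 3L) + 1L, ])
  }
  codes
}

codes_to_chars <- function(codes) c("A", "G", "C", "T")[codes]

#' Simulate a barcode community with a full truth table
#'
#' Draws a root sequence from the configured per-position base
#' frequencies (rejecting in-frame stops), then evolves a three-level
#' hierarchy (genus -> species -> individual) under the K2P substitution
#' process with per-codon-position rate multipliers, with branch lengths
#' chosen so that expected pairwise distances equal the configured
#' conspecific/congeneric/intergeneric depths. Each branch realizes its
#' expected substitution-event count (stochastic rounding), which keeps the
#' realized divergence pools tightly centered on the programmed depths and
#' cleanly separated. Functional lineages reject stop-creating mutations. Optionally replaces a fraction of individuals
#' with injected numt pseudogene copies (cycling stop / insertion /
#' deletion lesions). Byte-identical output for a given seed.
#'
#' @param cfg a [sim_config]
#' @return list with `alignment` (a [barcode_alignment]) and `truth` (class
#'   `sim_truth`: per-sequence species/genus, the depth parameters, the
#'   config, and a `numts` data frame of injected lesions)
#' @export
simulate_community <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  L <- cfg$seq_length
  posclass <- ((seq_len(L) - 1L) %% 3L) + 1L
  mult <- cfg$position_rates[posclass]
  t_ind <- cfg$conspecific_depth / 2
  t_sp <- (cfg$congeneric_depth - cfg$conspecific_depth) / 2
  t_gen <- (cfg$intergeneric_depth - cfg$congeneric_depth) / 2
  root <- random_root(cfg)
  n <- cfg$n_genera * cfg$species_per_genus * cfg$individuals_per_species
  mat <- matrix("", n, L)
  ids <- species <- genus <- character(n)
  row <- 0L
  for (g in seq_len(cfg$n_genera)) {
    gname <- sprintf("Genus%02d", g)
    ganc <- evolve_branch(root, t_gen, mult, cfg$kappa)
    for (s in seq_len(cfg$species_per_genus)) {
      spname <- sprintf("%s sp%02d", gname, s)
      sanc <- evolve_branch(ganc, t_sp, mult, cfg$kappa)
      for (i in seq_len(cfg$individuals_per_species)) {
        row <- row + 1L
        mat[row, ] <- codes_to_chars(
          evolve_branch(sanc, t_ind, mult, cfg$kappa))
        ids[row] <- sprintf("%s_sp%02d_%d", gname, s, i)
        species[row] <- spname
        genus[row] <- gname
      }
    }
  }
  rownames(mat) <- ids
  meta <- data.frame(seq_id = ids, species = species, genus = genus,
                     site = "", accession = "", stringsAsFactors = FALSE)
  aln <- barcode_alignment(mat, meta, frame_offset = 0)
  truth <- structure(list(
    sequences = meta[, c("seq_id", "species", "genus")],
    depths = c(conspecific = cfg$conspecific_depth,
               congeneric = cfg$congeneric_depth,
               intergeneric = cfg$intergeneric_depth),
    config = cfg,
    numts = data.frame(seq_id = character(), type = character(),
                       position = integer(), stringsAsFactors = FALSE)),
    class = "sim_truth")
  if (cfg$numt_rate > 0) {
    n_numt <- max(1L, round(cfg$numt_rate * n))
    targets <- sample(ids, n_numt)
    types <- rep(c("stop", "insertion", "deletion"), length.out = n_numt)
    for (k in seq_len(n_numt)) {
      res <- inject_numt(aln, targets[k], lesion = list(type = types[k]),
                         kappa = cfg$kappa)
      aln <- res$alignment
      truth$numts <- rbind(truth$numts, res$truth_row)
    }
  }
  list(alignment = aln, truth = truth)
}

#' True model distance between two simulated sequences
#' @param truth a `sim_truth`
#' @return symmetric matrix of the expected pairwise distances implied by
#'   the simulation hierarchy (0 on the diagonal)
#' @export
true_distance_matrix <- function(truth) {
  s <- truth$sequences
  n <- nrow(s)
  same_sp <- outer(s$species, s$species, `==`)
  same_gen <- outer(s$genus, s$genus, `==`)
  d <- matrix(truth$depths["intergeneric"], n, n,
              dimnames = list(s$seq_id, s$seq_id))
  d[same_gen] <- truth$depths["congeneric"]
  d[same_sp] <- truth$depths["conspecific"]
  diag(d) <- 0
  d
}

#' Inject a numt pseudogene lesion into one community sequence
#'
#' Replaces the chosen record with a pseudogene copy: background
#' substitutions at relaxed, codon-position-uniform rates (pseudogenes are
#' free of coding constraint) followed by the requested lesion — an
#' internal stop codon, a 1-bp insertion (a new alignment column in which
#' every other sequence gains a gap), a 1-bp deletion (a gap in the
#' record), or no lesion.
#'
#' @param aln a [barcode_alignment]
#' @param seq_id which record to mutate
#' @param lesion list with `type` in `"stop"`, `"insertion"`, `"deletion"`,
#'   `"none"`, and optionally `codon` (1-based codon index, for stops) or
#'   `position` (1-based aligned column, for indels); unset positions are
#'   drawn at random
#' @param extra_divergence expected background substitutions/site applied
#'   uniformly across codon positions (default 0.02)
#' @param kappa ts/tv rate ratio of the background process
#' @return list with the modified `alignment` and `truth_row` (data frame:
#'   seq_id, type, position — the aligned column of the lesion, or the
#'   first column of the stop codon)
#' @export
inject_numt <- function(aln, seq_id, lesion = list(type = "stop"),
                        extra_divergence = 0.02, kappa = 1.4) {
  stopifnot(seq_id %in% rownames(aln$mat))
  type <- match.arg(lesion$type, c("stop", "insertion", "deletion", "none"))
  L <- aln_length(aln)
  rec <- aln$mat[seq_id, ]
  nongap <- which(rec != "-")
  codes <- encode_seq(rec[nongap])
  if (any(codes == 0L)) codes[codes == 0L] <- sample(1:4, sum(codes == 0L),
                                                     replace = TRUE)
  codes <- k2p_evolve(codes, extra_divergence, kappa)
  rec[nongap] <- codes_to_chars(codes)
  pos <- NA_integer_
  if (type == "stop") {
    f <- aln$frame_offset
    ncod <- (length(nongap) - f) %/% 3L
    codon <- if (!is.null(lesion$codon)) lesion$codon
             else sample(2:(ncod - 1L), 1L)
    if (codon < 1L || codon > ncod) stop("stop codon index out of range")
    cols <- nongap[f + 3L * (codon - 1L) + 1:3]
    rec[cols] <- c("T", "A", "A")
    pos <- cols[1L]
    aln$mat[seq_id, ] <- rec
  } else if (type == "deletion") {
    pos <- if (!is.null(lesion$position)) lesion$position
           else sample(nongap, 1L)
    if (pos < 1L || pos > L) stop("deletion position out of range")
    rec[pos] <- "-"
    aln$mat[seq_id, ] <- rec
  } else if (type == "insertion") {
    pos <- if (!is.null(lesion$position)) lesion$position
           else sample.int(L, 1L)
    if (pos < 1L || pos > L + 1L) stop("insertion position out of range")
    newcol <- rep("-", n_seq(aln))
    names(newcol) <- rownames(aln$mat)
    newcol[seq_id] <- codes_to_chars(sample(1:4, 1L))
    left <- if (pos > 1L) aln$mat[, 1:(pos - 1L), drop = FALSE] else NULL
    right <- if (pos <= L) aln$mat[, pos:L, drop = FALSE] else NULL
    aln$mat <- cbind(left, newcol, right, deparse.level = 0)
    rownames(aln$mat) <- names(newcol)
    aln$mat[seq_id, ] <- c(if (pos > 1L) rec[1:(pos - 1L)],
                           newcol[seq_id], if (pos <= L) rec[pos:L])
  } else {
    aln$mat[seq_id, ] <- rec
  }
  list(alignment = aln,
       truth_row = data.frame(seq_id = seq_id, type = type,
                              position = as.integer(pos),
                              stringsAsFactors = FALSE))
}

#' Simulate one sequence pair at a given true K2P distance
#'
#' The ancestor is drawn uniformly over A/C/G/T (or from `base_freqs`) and
#' one copy is evolved to total distance `d_true` under the K2P process,
#' optionally with per-codon-position rate multipliers (normalized to mean
#' 1, so `d_true` stays the expected sitewise distance).
#'
#' @param d_true expected substitutions per site (>= 0)
#' @param kappa ts/tv rate ratio
#' @param length sequence length
#' @param position_rates optional relative rates at codon positions 1,2,3;
#'   `NULL` for homogeneous sites
#' @param base_freqs optional 3x4 per-position root frequencies
#' @param seed optional seed (uses the current RNG state when `NULL`)
#' @return a two-record [barcode_alignment] ("seq1", "seq2")
#' @export
simulate_pair <- function(d_true, kappa = 1.4, length = 650L,
                          position_rates = NULL, base_freqs = NULL,
                          seed = NULL) {
  if (!is.finite(d_true) || d_true < 0) stop("d_true out of domain")
  if (!is.null(seed)) set.seed(as.integer(seed))
  posclass <- ((seq_len(length) - 1L) %% 3L) + 1L
  code_of <- c(A = 1L, C = 3L, G = 2L, T = 4L)
  if (is.null(base_freqs)) {
    root <- sample(1:4, length, replace = TRUE)
  } else {
    root <- integer(length)
    for (p in 1:3)
      root[posclass == p] <- sample(code_of, sum(posclass == p),
                                    replace = TRUE, prob = base_freqs[p, ])
  }
  t <- if (is.null(position_rates)) rep(d_true, length)
       else d_true * (position_rates / mean(position_rates))[posclass]
  child <- k2p_evolve(root, t, kappa)
  mat <- rbind(seq1 = codes_to_chars(root), seq2 = codes_to_chars(child))
  barcode_alignment(mat, frame_offset = 0)
}
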