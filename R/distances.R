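# Integer encoding used throughout: A=1, G=2 (purines), C=3, T=4
# (pyrimidines), anything else (gap, N, IUPAC ambiguity) = 0 and is
# excluded by pairwise deletion.
.BASE_CODES <- c(A = 1L, G = 2L, C = 3L, T = 4L)

encode_alignment <- function(aln) {
  mat <- if (inherits(aln, "barcode_alignment")) aln$mat else aln
  codes <- .BASE_CODES[mat]
  codes[is.na(codes)] <- 0L
  matrix(codes, nrow = nrow(mat), dimnames = dimnames(mat))
}

encode_seq <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1L]]
  codes <- .BASE_CODES[toupper(x)]
  codes[is.na(codes)] <- 0L
  unname(codes)
}

#' Transition/transversion counts for one sequence pair
#'
#' Compares two aligned sequences under pairwise deletion: any column where
#' either sequence carries a gap or a non-ACGT symbol is excluded from the
#' compared length L. Transitions are purine-purine (A/G) or
#' pyrimidine-pyrimidine (C/T) mismatches; all other mismatches are
#' transversions.
#'
#' @param a,b aligned sequences of equal length (strings or character
#'   vectors)
#' @return A list of class `pair_counts` with `L` (compared sites), `n_ts`,
#'   `n_tv`, and the proportions `P = n_ts/L`, `Q = n_tv/L`.
#' @export
count_pair <- function(a, b) {
  ca <- encode_seq(a); cb <- encode_seq(b)
  if (length(ca) != length(cb))
    stop("sequences differ in aligned length (", length(ca), " vs ",
         length(cb), ")")
  ok <- ca > 0L & cb > 0L
  L <- sum(ok)
  if (L == 0L) stop("no comparable sites between the two sequences")
  ca <- ca[ok]; cb <- cb[ok]
  diff <- ca != cb
  ts <- diff & ((ca <= 2L) == (cb <= 2L))
  n_ts <- sum(ts); n_tv <- sum(diff) - n_ts
  structure(list(L = L, n_ts = n_ts, n_tv = n_tv,
                 P = n_ts / L, Q = n_tv / L),
            class = "pair_counts")
}

as_PQ <- function(c_or_P, Q) {
  if (inherits(c_or_P, "pair_counts")) c(c_or_P$P, c_or_P$Q)
  else c(c_or_P, Q)
}

#' Kimura two-parameter distances
#'
#' `k2p()` returns the total K2P distance
#' \deqn{d = -\tfrac12 \ln\{(1-2P-Q)\sqrt{1-2Q}\},}
#' `k2p_transition()` its transitional component
#' \eqn{d_s = -\tfrac12\ln(1-2P-Q) + \tfrac14\ln(1-2Q)} and
#' `k2p_transversion()` the transversional component
#' \eqn{d_v = -\tfrac12\ln(1-2Q)}, where P and Q are the transition and
#' transversion proportions. The components sum exactly to the total.
#' Saturated pairs (either logarithm argument non-positive) return `NA`
#' rather than raising, so that large pooled analyses can carry them as
#' flagged-undefined entries.
#'
#' @param c a `pair_counts` object, or the numeric transition proportion P
#' @param Q numeric transversion proportion (ignored when `c` is a
#'   `pair_counts`)
#' @return numeric distance, `NA` on saturation
#' @export
k2p <- function(c, Q = NULL) {
  pq <- as_PQ(c, Q); P <- pq[1L]; Qv <- pq[2L]
  a1 <- 1 - 2 * P - Qv; a2 <- 1 - 2 * Qv
  if (is.na(a1) || a1 <= 0 || a2 <= 0) return(NA_real_)
  -0.5 * log(a1 * sqrt(a2)) + 0
}

#' @rdname k2p
#' @export
k2p_transition <- function(c, Q = NULL) {
  pq <- as_PQ(c, Q); P <- pq[1L]; Qv <- pq[2L]
  a1 <- 1 - 2 * P - Qv; a2 <- 1 - 2 * Qv
  if (is.na(a1) || a1 <= 0 || a2 <= 0) return(NA_real_)
  -0.5 * log(a1) + 0.25 * log(a2)
}

#' @rdname k2p
#' @export
k2p_transversion <- function(c, Q = NULL) {
  pq <- as_PQ(c, Q); Qv <- pq[2L]
  a2 <- 1 - 2 * Qv
  if (is.na(a2) || a2 <= 0) return(NA_real_)
  -0.5 * log(a2) + 0
}

#' Labeled symmetric distance matrix
#'
#' @param values square symmetric numeric matrix with dimnames; `NA`
#'   entries flag saturated (undefined) pairs and are never silently
#'   dropped.
#' @param kind one of "k2p_total", "k2p_transition", "k2p_transversion",
#'   "p_distance"
#' @return object of class `barcode_dist`
#' @export
barcode_dist <- function(values, kind = c("k2p_total", "k2p_transition",
                                          "k2p_transversion", "p_distance")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            !is.null(rownames(values)))
  off <- abs(values - t(values))
  if (any(off > 1e-12, na.rm = TRUE)) stop("matrix is not symmetric")
  diag(values) <- 0
  structure(list(labels = rownames(values), values = values, kind = kind),
            class = "barcode_dist")
}

#' @export
as.matrix.barcode_dist <- function(x, ...) x$values

#' @export
print.barcode_dist <- function(x, ...) {
  n <- length(x$labels)
  cat("barcode_dist (", x$kind, "): ", n, " taxa, ",
      sum(is.na(x$values[upper.tri(x$values)])), " undefined pairs\n",
      sep = "")
  invisible(x)
}

# Per-pair count matrices (n_ts, n_tv, L) over all unordered pairs, row-
# vectorized: row i is compared against rows i+1..n in one matrix operation.
# deletion = "complete" first drops every column containing any gap or
# ambiguity in any sequence.
#' Pairwise transition/transversion count matrices
#'
#' @param aln a [barcode_alignment]
#' @param deletion "pairwise" (drop invalid columns per pair) or "complete"
#'   (drop any column invalid in any sequence before comparing)
#' @return list of symmetric integer matrices `TS`, `TV`, `L`
#' @export
pair_counts_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  S <- encode_alignment(aln)
  if (deletion == "complete") {
    keep <- colSums(S == 0L) == 0L
    if (!any(keep)) stop("no comparable sites after complete deletion")
    S <- S[, keep, drop = FALSE]
  }
  n <- nrow(S); L <- ncol(S)
  TS <- TV <- Lm <- matrix(0L, n, n, dimnames = list(rownames(S), rownames(S)))
  pur <- S <= 2L & S > 0L
  valid <- S > 0L
  for (i in seq_len(n - 1L)) {
    rows <- (i + 1L):n
    M <- S[rows, , drop = FALSE]
    vi <- matrix(valid[i, ], length(rows), L, byrow = TRUE)
    ok <- (M > 0L) & vi
    d <- (M != matrix(S[i, ], length(rows), L, byrow = TRUE)) & ok
    ts <- d & ((M <= 2L & M > 0L) == matrix(pur[i, ], length(rows), L,
                                            byrow = TRUE))
    TS[i, rows] <- TS[rows, i] <- as.integer(rowSums(ts))
    TV[i, rows] <- TV[rows, i] <- as.integer(rowSums(d) - rowSums(ts))
    Lm[i, rows] <- Lm[rows, i] <- as.integer(rowSums(ok))
  }
  diag(Lm) <- L
  list(TS = TS, TV = TV, L = Lm)
}

#' Pairwise distance matrix over an alignment
#'
#' Computes all unordered pairwise distances of the requested kind.
#' Saturated pairs are flagged `NA`. A pair with zero comparable sites is an
#' error naming the pair.
#'
#' @param aln a [barcode_alignment] (at least 2 records)
#' @param kind distance kind (see [barcode_dist])
#' @param deletion column-deletion mode, see [pair_counts_matrix]
#' @param counts optional precomputed [pair_counts_matrix] result
#' @return a [barcode_dist]
#' @export
pairwise_matrix <- function(aln, kind = c("k2p_total", "k2p_transition",
                                          "k2p_transversion", "p_distance"),
                            deletion = c("pairwise", "complete"),
                            counts = NULL) {
  kind <- match.arg(kind)
  if (n_seq(aln) < 2L) stop("need at least 2 sequences")
  if (is.null(counts)) counts <- pair_counts_matrix(aln, deletion)
  Lm <- counts$L
  zero <- which(Lm == 0L & upper.tri(Lm), arr.ind = TRUE)
  if (nrow(zero))
    stop("no comparable sites for pair (",
         rownames(Lm)[zero[1L, 1L]], ", ", colnames(Lm)[zero[1L, 2L]], ")")
  P <- counts$TS / Lm; Q <- counts$TV / Lm
  v <- suppressWarnings(switch(kind,
    p_distance = P + Q,
    k2p_total = {
      a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
      out <- -0.5 * log(a1 * sqrt(a2)) + 0
      out[a1 <= 0 | a2 <= 0] <- NA_real_; out
    },
    k2p_transition = {
      a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
      out <- -0.5 * log(a1) + 0.25 * log(a2)
      out[a1 <= 0 | a2 <= 0] <- NA_real_; out
    },
    k2p_transversion = {
      a2 <- 1 - 2 * Q
      out <- -0.5 * log(a2) + 0
      out[a2 <= 0] <- NA_real_; out
    }))
  diag(v) <- 0
  barcode_dist(v, kind = kind)
}

#' Mean transition/transversion ratio (R-value)
#'
#' The unweighted mean over sequence pairs of the per-pair count ratio
#' n_ts/n_tv. Pairs with zero transversions are excluded from the mean and
#' their number reported in the `n_excluded` attribute.
#'
#' @param counts result of [pair_counts_matrix], or a list of
#'   `pair_counts`
#' @return mean ratio (attribute `n_excluded` gives the number of
#'   zero-transversion pairs); `NA` with a warning when every pair has zero
#'   transversions
#' @export
r_value <- function(counts) {
  if (is.list(counts) && !is.null(counts$TS)) {
    ut <- upper.tri(counts$TS)
    ts <- counts$TS[ut]; tv <- counts$TV[ut]
  } else {
    ts <- vapply(counts, `[[`, 0, "n_ts")
    tv <- vapply(counts, `[[`, 0, "n_tv")
  }
  use <- tv > 0
  n_excluded <- sum(!use)
  if (!any(use)) {
    warning("R-value undefined: every pair has zero transversions")
    return(structure(NA_real_, n_excluded = n_excluded))
  }
  structure(mean(ts[use] / tv[use]), n_excluded = n_excluded)
}

#' Within- and between-taxon distance summaries
#'
#' Partitions the pairwise distances of a matrix by a seq_id-to-taxon
#' grouping: per-taxon within statistics (mean and maximum), per taxon-pair
#' between statistics (mean and minimum), and the three-category pooling of
#' all defined pairs into conspecific, congeneric-heterospecific and
#' intergeneric distances (genus = first token of the taxon name).
#' Undefined (NA) entries are excluded and counted. Singleton taxa yield NA
#' within-taxon statistics.
#'
#' @param m a [barcode_dist]
#' @param grouping named character vector mapping every label of `m` to a
#'   taxon
#' @return list of class `group_summary` with `per_taxon`, `per_pair`,
#'   `pools` (numeric vectors `conspecific`, `congeneric`, `intergeneric`),
#'   and `n_undefined`
#' @export
group_summary <- function(m, grouping) {
  v <- as.matrix(m)
  labs <- rownames(v)
  if (!all(labs %in% names(grouping)))
    stop("grouping does not cover labels: ",
         paste(setdiff(labs, names(grouping))[1:3], collapse = ", "))
  taxon <- unname(grouping[labs])
  genus <- vapply(strsplit(taxon, "[ _]"), `[`, "", 1L)
  n <- length(labs)
  ij <- which(upper.tri(v), arr.ind = TRUE)
  d <- v[upper.tri(v)]
  ti <- taxon[ij[, 1L]]; tj <- taxon[ij[, 2L]]
  gi <- genus[ij[, 1L]]; gj <- genus[ij[, 2L]]
  defined <- !is.na(d)
  n_undefined <- sum(!defined)
  cat3 <- ifelse(ti == tj, "conspecific",
                 ifelse(gi == gj, "congeneric", "intergeneric"))
  pools <- list(
    conspecific = d[defined & cat3 == "conspecific"],
    congeneric = d[defined & cat3 == "congeneric"],
    intergeneric = d[defined & cat3 == "intergeneric"])
  taxa <- sort(unique(taxon))
  per_taxon <- do.call(rbind, lapply(taxa, function(t) {
    dw <- d[defined & ti == t & tj == t]
    data.frame(taxon = t, n_seq = sum(taxon == t), n_pairs = length(dw),
               mean_within = if (length(dw)) mean(dw) else NA_real_,
               max_within = if (length(dw)) max(dw) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  pair_key <- ifelse(ti < tj, paste(ti, tj, sep = "\r"),
                     paste(tj, ti, sep = "\r"))
  between <- defined & ti != tj
  per_pair <- NULL
  if (any(between)) {
    sp_mean <- tapply(d[between], pair_key[between], mean)
    sp_min <- tapply(d[between], pair_key[between], min)
    sp_n <- tapply(d[between], pair_key[between], length)
    ks <- strsplit(names(sp_mean), "\r", fixed = TRUE)
    per_pair <- data.frame(
      taxon_a = vapply(ks, `[`, "", 1L), taxon_b = vapply(ks, `[`, "", 2L),
      n_pairs = as.integer(sp_n), mean_between = as.numeric(sp_mean),
      min_between = as.numeric(sp_min), stringsAsFactors = FALSE)
    rownames(per_pair) <- NULL
  }
  structure(list(per_taxon = per_taxon, per_pair = per_pair, pools = pools,
                 n_undefined = n_undefined, kind = m$kind),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("group_summary (", x$kind, "): ", nrow(x$per_taxon), " taxa\n",
      sep = "")
  for (p in names(x$pools))
    cat(sprintf("  %-13s n=%d%s\n", p, length(x$pools[[p]]),
                if (length(x$pools[[p]]))
                  sprintf(" range %.4f-%.4f mean %.4f",
                          min(x$pools[[p]]), max(x$pools[[p]]),
                          mean(x$pools[[p]])) else ""))
  if (x$n_undefined) cat("  undefined pairs excluded:", x$n_undefined, "\n")
  invisible(x)
}
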