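#' Delimitation thresholds
#'
#' The two distance thresholds of barcoding-gap species delimitation: a
#' K2P divergence above which sequences are treated as heterospecific
#' (default 2%), and a transversion-distance boundary separating most
#' species pairs (default 1.1%).
#'
#' @param theta_k2p K2P threshold (default 0.02)
#' @param theta_tv transversion-distance threshold (default 0.011)
#' @return list of class `barcode_thresholds`
#' @export
barcode_thresholds <- function(theta_k2p = 0.02, theta_tv = 0.011) {
  stopifnot(theta_tv > 0, theta_tv < theta_k2p, theta_k2p < 1)
  structure(list(theta_k2p = theta_k2p, theta_tv = theta_tv),
            class = "barcode_thresholds")
}

#' Default exclusion set: the Culex mimeticus species subgroup
#'
#' Species of the Culex mimeticus subgroup show anomalous COI divergence
#' patterns (morphologically distinct members sharing near-identical
#' barcodes, plausibly from Wolbachia-driven sweeps) and are conventionally
#' excluded from barcoding-gap pooling. Membership is configurable; this
#' ships the core members.
#'
#' @return character vector of species names
#' @export
mimeticus_subgroup <- function() {
  c("Culex mimulus", "Culex mimeticus", "Culex murrelli")
}

#' Barcoding-gap summary of a distance matrix pair
#'
#' Pools the defined pairwise distances into conspecific, congeneric
#' (heterospecific, same genus) and intergeneric categories for both the
#' K2P total and transversion matrices, after removing any excluded taxa,
#' and reports pool ranges/means, the ratio of mean congeneric to mean
#' conspecific divergence, and the fraction of conspecific
#' (resp. congeneric) pairs below (resp. above) the K2P threshold.
#'
#' @param m_total K2P total [barcode_dist]
#' @param m_tv K2P transversion [barcode_dist] over the same labels
#' @param grouping named vector seq_id -> species
#' @param thresholds a [barcode_thresholds]
#' @param exclusions character vector of taxa removed before pooling
#'   (e.g. a known problematic species subgroup)
#' @return list of class `gap_summary`: `pools` (per kind), `stats` (range
#'   and mean per pool and kind), `ratio_congeneric_over_conspecific`,
#'   `pct_conspecific_below_theta`, `pct_congeneric_above_theta`,
#'   `groups_total`, `groups_tv` (the underlying [group_summary]s),
#'   `thresholds`, `excluded`
#' @export
gap_summary <- function(m_total, m_tv, grouping,
                        thresholds = barcode_thresholds(),
                        exclusions = character()) {
  stopifnot(inherits(thresholds, "barcode_thresholds"))
  keep_ids <- names(grouping)[!grouping %in% exclusions]
  sub <- function(m) {
    ids <- intersect(m$labels, keep_ids)
    barcode_dist(as.matrix(m)[ids, ids, drop = FALSE], m$kind)
  }
  mt <- sub(m_total); mv <- sub(m_tv)
  gt <- group_summary(mt, grouping)
  gv <- group_summary(mv, grouping)
  pool_stats <- function(g) {
    do.call(rbind, lapply(names(g$pools), function(p) {
      x <- g$pools[[p]]
      data.frame(pool = p, n = length(x),
                 min = if (length(x)) min(x) else NA_real_,
                 max = if (length(x)) max(x) else NA_real_,
                 mean = if (length(x)) mean(x) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  con <- gt$pools$conspecific; cog <- gt$pools$congeneric
  ratio <- if (length(con) && mean(con) > 0 && length(cog))
    mean(cog) / mean(con) else NA_real_
  structure(list(
    pools = list(k2p_total = gt$pools, k2p_transversion = gv$pools),
    stats = list(k2p_total = pool_stats(gt),
                 k2p_transversion = pool_stats(gv)),
    ratio_congeneric_over_conspecific = ratio,
    pct_conspecific_below_theta =
      if (length(con)) 100 * mean(con < thresholds$theta_k2p) else NA_real_,
    pct_congeneric_above_theta =
      if (length(cog)) 100 * mean(cog > thresholds$theta_k2p) else NA_real_,
    groups_total = gt, groups_tv = gv,
    thresholds = thresholds, excluded = exclusions),
    class = "gap_summary")
}

#' @export
print.gap_summary <- function(x, ...) {
  cat("gap_summary (theta_k2p =", x$thresholds$theta_k2p, ", theta_tv =",
      x$thresholds$theta_tv, ")\n")
  s <- x$stats$k2p_total
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-13s n=%-6d K2P %s\n", s$pool[i], s$n[i],
                if (s$n[i]) sprintf("range %.4f-%.4f mean %.4f",
                                    s$min[i], s$max[i], s$mean[i]) else "-"))
  cat(sprintf("  congeneric/conspecific mean ratio: %.1f\n",
              x$ratio_congeneric_over_conspecific))
  cat(sprintf("  %% conspecific < theta: %.1f; %% congeneric > theta: %.1f\n",
              x$pct_conspecific_below_theta, x$pct_congeneric_above_theta))
  if (length(x$excluded))
    cat("  excluded taxa:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Histogram of the three distance pools
#' @param x a [gap_summary]
#' @param kind which distance kind to plot
#' @param breaks passed to [graphics::hist]
#' @param ... further graphical parameters
#' @export
plot.gap_summary <- function(x, kind = c("k2p_total", "k2p_transversion"),
                             breaks = 40, ...) {
  kind <- match.arg(kind)
  pools <- x$pools[[kind]]
  all <- unlist(pools)
  if (!length(all)) stop("no defined distances to plot")
  h <- graphics::hist(all, breaks = breaks, plot = FALSE)
  cols <- c(conspecific = "grey30", congeneric = "steelblue",
            intergeneric = "orange")
  counts <- sapply(names(pools), function(p)
    graphics::hist(pools[[p]], breaks = h$breaks, plot = FALSE)$counts)
  graphics::barplot(t(counts), names.arg = sprintf("%.2f", h$mids),
                    col = cols, border = NA, las = 2,
                    xlab = paste(kind, "distance"), ylab = "pairs", ...)
  graphics::legend("topright", legend = names(pools), fill = cols,
                   bty = "n")
  invisible(x)
}

#' Assign a query sequence to a species by nearest reference
#'
#' Best-close-match assignment: the query is compared (K2P) to every
#' reference individual; it is assigned the nearest reference's species iff
#' that distance is below the K2P threshold, otherwise "unassigned".
#' Queries equidistant from references of different species are
#' "ambiguous" with all tied species reported. The top three nearest
#' neighbors are always returned.
#'
#' @param query aligned query sequence (string) in the reference coordinate
#'   system
#' @param refs reference [barcode_alignment] with species metadata
#' @param thresholds a [barcode_thresholds]
#' @return list of class `barcode_assignment`: `assignment` (species name,
#'   "unassigned" or "ambiguous"), `distance`, `tied_species`, `top3`
#'   (data frame seq_id/species/distance)
#' @export
classify_query <- function(query, refs, thresholds = barcode_thresholds()) {
  q <- encode_seq(query)
  if (length(q) != aln_length(refs))
    stop("query length does not match reference alignment")
  S <- encode_alignment(refs)
  ok <- t(S) > 0L & q > 0L
  d <- vapply(seq_len(nrow(S)), function(i) {
    sel <- ok[, i]
    L <- sum(sel)
    if (L == 0L) return(NA_real_)
    diff <- S[i, sel] != q[sel]
    ts <- sum(diff & ((S[i, sel] <= 2L) == (q[sel] <= 2L)))
    k2p(ts / L, (sum(diff) - ts) / L)
  }, 0)
  if (all(is.na(d))) stop("all query-reference distances undefined")
  ord <- order(d, rownames(S))           # canonical: distance then label
  top3 <- data.frame(seq_id = rownames(S)[ord][1:min(3L, length(ord))],
                     species = refs$meta$species[ord][1:min(3L, length(ord))],
                     distance = d[ord][1:min(3L, length(ord))],
                     stringsAsFactors = FALSE)
  dmin <- min(d, na.rm = TRUE)
  tied <- sort(unique(refs$meta$species[!is.na(d) & d == dmin]))
  assignment <- if (dmin >= thresholds$theta_k2p) "unassigned"
                else if (length(tied) > 1L) "ambiguous"
                else tied
  structure(list(assignment = assignment, distance = dmin,
                 tied_species = tied, top3 = top3),
            class = "barcode_assignment")
}

#' @export
print.barcode_assignment <- function(x, ...) {
  cat("assignment:", x$assignment, sprintf("(d = %.4f)\n", x$distance))
  print(x$top3)
  invisible(x)
}

#' Flag cryptic-species and synonymy candidates
#'
#' Cryptic candidates: species whose maximum within-species K2P distance
#' exceeds the K2P threshold; sub-flagged "strong" when the maximum
#' within-species transversion distance also exceeds the transversion
#' boundary. Synonymy candidates: species pairs whose between-species mean
#' K2P distance is below the K2P threshold; sub-flagged "plesiomorphic
#' pair" when the between-species mean transversion distance is at or
#' below the transversion boundary.
#'
#' @param gs a [gap_summary] (carries per-taxon/per-pair statistics for
#'   both kinds)
#' @param thresholds a [barcode_thresholds]; defaults to the ones stored
#'   in `gs`
#' @return list with data frames `cryptic` (species, max_within_k2p,
#'   max_within_tv, strong) and `synonymy` (taxon_a, taxon_b,
#'   mean_between_k2p, mean_between_tv, plesiomorphic)
#' @export
flag_taxa <- function(gs, thresholds = NULL) {
  stopifnot(inherits(gs, "gap_summary"))
  if (is.null(thresholds)) thresholds <- gs$thresholds
  pt <- gs$groups_total$per_taxon; pv <- gs$groups_tv$per_taxon
  tv_max <- pv$max_within[match(pt$taxon, pv$taxon)]
  cry <- !is.na(pt$max_within) & pt$max_within > thresholds$theta_k2p
  cryptic <- data.frame(species = pt$taxon[cry],
                        max_within_k2p = pt$max_within[cry],
                        max_within_tv = tv_max[cry],
                        strong = !is.na(tv_max[cry]) &
                                 tv_max[cry] > thresholds$theta_tv,
                        stringsAsFactors = FALSE)
  synonymy <- data.frame(taxon_a = character(), taxon_b = character(),
                         mean_between_k2p = numeric(),
                         mean_between_tv = numeric(),
                         plesiomorphic = logical(),
                         stringsAsFactors = FALSE)
  bt <- gs$groups_total$per_pair; bv <- gs$groups_tv$per_pair
  if (!is.null(bt)) {
    key <- paste(bt$taxon_a, bt$taxon_b, sep = "\r")
    keyv <- paste(bv$taxon_a, bv$taxon_b, sep = "\r")
    tvm <- bv$mean_between[match(key, keyv)]
    syn <- bt$mean_between < thresholds$theta_k2p
    synonymy <- data.frame(taxon_a = bt$taxon_a[syn],
                           taxon_b = bt$taxon_b[syn],
                           mean_between_k2p = bt$mean_between[syn],
                           mean_between_tv = tvm[syn],
                           plesiomorphic = !is.na(tvm[syn]) &
                                           tvm[syn] <= thresholds$theta_tv,
                           stringsAsFactors = FALSE)
  }
  list(cryptic = cryptic, synonymy = synonymy)
}

#' Transition/transversion distance versus total divergence
#'
#' Bins all defined sequence pairs by their total K2P divergence and
#' reports the per-bin mean transitional and transversional distance, plus
#' the crossover bin: the first bin in which the mean transversion
#' distance reaches or exceeds the mean transition distance (transversions
#' overtake transitions at deep divergence when the transition/transversion
#' rate ratio is below 1).
#'
#' @param counts result of [pair_counts_matrix]
#' @param bins numeric vector of bin breakpoints covering the observed
#'   range, or a single integer number of equal-width bins
#' @return data frame (class `ts_tv_curve`) with `bin_mid`, `n_pairs`,
#'   `mean_d`, `mean_ds`, `mean_dv`; attribute `crossover` gives the first
#'   crossover bin midpoint (`NA` when none)
#' @export
ts_tv_curve <- function(counts, bins = 20) {
  ut <- upper.tri(counts$L)
  P <- (counts$TS / counts$L)[ut]; Q <- (counts$TV / counts$L)[ut]
  a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
  def <- a1 > 0 & a2 > 0
  d <- -0.5 * log(a1[def] * sqrt(a2[def]))
  dv <- -0.5 * log(a2[def])
  ds <- d - dv
  if (length(bins) == 1L)
    bins <- seq(0, max(d) * (1 + 1e-9), length.out = bins + 1L)
  cuts <- cut(d, breaks = bins, include.lowest = TRUE)
  mids <- (bins[-1L] + bins[-length(bins)]) / 2
  keep <- levels(cuts)[tabulate(cuts, nbins = nlevels(cuts)) > 0L]
  out <- do.call(rbind, lapply(which(levels(cuts) %in% keep), function(i) {
    sel <- as.integer(cuts) == i
    data.frame(bin_mid = mids[i], n_pairs = sum(sel),
               mean_d = mean(d[sel]), mean_ds = mean(ds[sel]),
               mean_dv = mean(dv[sel]))
  }))
  cross <- out$bin_mid[out$mean_dv >= out$mean_ds]
  attr(out, "crossover") <- if (length(cross)) cross[1L] else NA_real_
  class(out) <- c("ts_tv_curve", "data.frame")
  out
}
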