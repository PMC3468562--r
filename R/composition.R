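codon_positions <- function(aln) {
  # codon position of column c (1-based): ((c - 1 - frame_offset) mod 3) + 1
  ((seq_len(aln_length(aln)) - 1L - aln$frame_offset) %% 3L) + 1L
}

count_bases <- function(mat_rows, pos) {
  # counts[pos 1..3 + pooled, base] over valid A/C/G/T cells
  out <- matrix(0, 4L, 4L, dimnames = list(c("all", "1", "2", "3"),
                                           c("A", "C", "G", "T")))
  for (p in 1:3) {
    cells <- mat_rows[, pos == p, drop = FALSE]
    tab <- table(factor(cells, levels = c("A", "C", "G", "T")))
    out[p + 1L, ] <- as.numeric(tab)
  }
  out["all", ] <- colSums(out[2:4, , drop = FALSE])
  out
}

counts_to_profile <- function(counts, unit) {
  freq <- counts / rowSums(counts)
  data.frame(unit = unit, pos = rownames(counts),
             A = freq[, "A"], C = freq[, "C"], G = freq[, "G"],
             T = freq[, "T"], at = freq[, "A"] + freq[, "T"],
             n_sites = rowSums(counts), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-codon-position nucleotide composition
#'
#' Computes A/C/G/T frequencies at each codon position (1, 2, 3) and pooled
#' over all positions, excluding gaps and ambiguity codes from the
#' denominators, plus the A+T content. COI barcodes show a strong A+T bias,
#' especially at third positions.
#'
#' Scope "dataset" pools counts over all sequences (so the dataset profile
#' is the site-count-weighted mean of per-sequence profiles); "sequence"
#' returns one profile per record; "genus" (or any grouping) returns the
#' unweighted average of the per-sequence frequency profiles within each
#' group.
#'
#' @param aln a [barcode_alignment] with at least 3 columns
#' @param scope "dataset", "genus" or "sequence"
#' @param grouping optional named vector seq_id -> group used when
#'   `scope = "genus"`; defaults to the genus metadata field
#' @return data frame of class `composition_profile` with columns `unit`,
#'   `pos` ("all","1","2","3"), `A`, `C`, `G`, `T`, `at`, `n_sites`
#' @export
composition_profile <- function(aln, scope = c("dataset", "genus",
                                               "sequence"),
                                grouping = NULL) {
  scope <- match.arg(scope)
  if (aln_length(aln) < 3L) stop("alignment shorter than 3 columns")
  pos <- codon_positions(aln)
  if (scope == "dataset") {
    prof <- counts_to_profile(count_bases(aln$mat, pos), "dataset")
  } else if (scope == "sequence") {
    prof <- do.call(rbind, lapply(seq_len(n_seq(aln)), function(i)
      counts_to_profile(count_bases(aln$mat[i, , drop = FALSE], pos),
                        rownames(aln$mat)[i])))
  } else {
    if (is.null(grouping))
      grouping <- setNames(aln$meta$genus, aln$meta$seq_id)
    per_seq <- composition_profile(aln, "sequence")
    grp <- unname(grouping[per_seq$unit])
    prof <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
      sub <- per_seq[grp == g, ]
      agg <- stats::aggregate(sub[, c("A", "C", "G", "T", "at")],
                              list(pos = sub$pos), mean)
      ns <- stats::aggregate(sub$n_sites, list(pos = sub$pos), sum)
      data.frame(unit = g, agg[match(c("all", "1", "2", "3"), agg$pos), ],
                 n_sites = ns$x[match(c("all", "1", "2", "3"), ns$pos)],
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }
  class(prof) <- c("composition_profile", "data.frame")
  prof
}

#' Report taxa/positions with a base frequency of exactly zero
#'
#' Mirrors checks such as the absence of any G at third codon positions in
#' particular genera.
#'
#' @param profile a [composition_profile]
#' @return data frame with columns `unit`, `pos`, `base` for every exact
#'   zero frequency (positions "1","2","3" only, the pooled row excluded)
#' @export
zero_base_check <- function(profile) {
  out <- data.frame(unit = character(), pos = character(),
                    base = character(), stringsAsFactors = FALSE)
  sub <- profile[profile$pos != "all", ]
  for (base in c("A", "C", "G", "T")) {
    z <- sub[[base]] == 0
    z[is.na(z)] <- FALSE
    if (any(z))
      out <- rbind(out, data.frame(unit = sub$unit[z], pos = sub$pos[z],
                                   base = base, stringsAsFactors = FALSE))
  }
  out[order(out$unit, out$pos, out$base), , drop = FALSE]
}

#' Write a composition profile as TSV (rows = units x positions)
#' @param profile a [composition_profile]
#' @param path output file
#' @export
write_composition_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
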