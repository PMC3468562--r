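#' Translate a nucleotide sequence under the invertebrate mitochondrial code
#'
#' Uses genetic-code table 5 (invertebrate mitochondrial), the code of
#' culicid COI: AGA/AGG encode Ser and TGA encodes Trp, so only TAA and TAG
#' are stops. Gaps are removed before translation, the trailing incomplete
#' codon is dropped, codons containing ambiguity codes translate to "X",
#' and stops are rendered "*".
#'
#' @param seq nucleotide sequence (string or character vector); gaps
#'   allowed and ignored
#' @param frame 0, 1 or 2: offset of the first codon position
#' @return protein string
#' @export
translate_mt <- function(seq, frame = 0) {
  stopifnot(frame %in% 0:2)
  if (length(seq) == 1L) seq <- strsplit(seq, "")[[1L]]
  seq <- toupper(seq)
  seq <- seq[seq != "-"]
  if (length(seq) == 0L) stop("empty sequence")
  if (length(seq) < frame + 3L) return("")
  aa <- seqinr::translate(seq, frame = frame, numcode = 5, ambiguous = FALSE)
  paste(aa, collapse = "")
}

#' Majority-rule consensus of an alignment
#'
#' Per-column majority character (among all characters including gaps);
#' ties are broken alphabetically for determinism. Usually computed within
#' species or over the whole dataset to provide the reference against
#' which candidate pseudogenes are screened.
#'
#' @param aln a [barcode_alignment]
#' @param grouping optional named vector seq_id -> group; when given, one
#'   consensus per group is returned as a named character vector
#' @return consensus string, or named vector of strings per group
#' @export
consensus_sequence <- function(aln, grouping = NULL) {
  cons_of <- function(mat) {
    paste(apply(mat, 2L, function(col) {
      tab <- table(col)
      sort(names(tab)[tab == max(tab)])[1L]   # ties broken alphabetically
    }), collapse = "")
  }
  if (is.null(grouping)) return(cons_of(aln$mat))
  ids <- rownames(aln$mat)
  groups <- unname(grouping[ids])
  vapply(sort(unique(groups)), function(g)
    cons_of(aln$mat[groups == g, , drop = FALSE]), "")
}

#' Choose the reading frame minimizing internal stops
#'
#' Translates the (dataset or supplied) consensus in all three frames and
#' returns the frame with the fewest internal stop codons; ties go to the
#' smallest frame.
#'
#' @param aln a [barcode_alignment], or a consensus sequence string
#' @return frame offset in 0:2
#' @export
choose_frame <- function(aln) {
  cons <- if (inherits(aln, "barcode_alignment")) consensus_sequence(aln)
          else aln
  stops <- vapply(0:2, function(f) {
    aa <- translate_mt(cons, f)
    sum(strsplit(substr(aa, 1L, nchar(aa) - 1L), "")[[1L]] == "*")
  }, 0)
  which.min(stops) - 1L
}

# Exact two-sided multinomial goodness-of-fit test for 3 categories:
# p-value = total probability of all outcomes no more probable than the
# observed one under the null proportions. Enumeration over the
# (n+1)(n+2)/2 outcomes is vectorized in log space.
exact_multinomial_test <- function(x, prob) {
  stopifnot(length(x) == 3L, length(prob) == 3L)
  n <- sum(x)
  if (n == 0L) return(1)
  prob <- prob / sum(prob)
  g <- expand.grid(a = 0:n, b = 0:n)
  g <- g[g$a + g$b <= n, ]
  cc <- n - g$a - g$b
  lp <- function(a, b, c) lfactorial(n) - lfactorial(a) - lfactorial(b) -
    lfactorial(c) + a * log(prob[1]) + b * log(prob[2]) + c * log(prob[3])
  logp <- lp(g$a, g$b, cc)
  log_obs <- lp(x[1], x[2], x[3])
  min(sum(exp(logp[logp <= log_obs + 1e-9])), 1)
}

#' Screen one sequence for pseudogene (numt) signatures
#'
#' Compares an aligned record against a reference (typically the
#' within-species or dataset majority-rule consensus) and reports the
#' classic numt diagnostics: alignment indels (a gap in one of
#' record/reference but not the other), internal stop codons under the
#' invertebrate mitochondrial code, the codon-position profile of
#' nucleotide mismatches (functional COI accumulates substitutions in
#' roughly 5:1:18 proportions across positions 1:2:3, whereas numts drift
#' toward uniformity), amino-acid differences, and the K2P distance to the
#' reference.
#'
#' Verdicts: `"fail"` iff an internal stop or an indel is present;
#' `"suspect"` when the mismatch codon-position profile deviates from the
#' expected proportions (exact multinomial test, p < `p_cutoff`) without a
#' hard flag; otherwise `"pass"`.
#'
#' @param record aligned sequence (string) or a row index/seq_id into
#'   `aln` when used via [screen_alignment]
#' @param reference aligned reference sequence (string), same length
#' @param frame frame offset in 0:2
#' @param expected_ratio expected codon-position substitution proportions
#'   for functional sequences (default 5:1:18)
#' @param p_cutoff significance level of the suspect test
#' @return list of class `numt_report`: `seq_id`, `frame_used`,
#'   `has_internal_stop`, `first_stop_codon`, `has_indel`, `codon_ratio`
#'   (n1,n2,n3), `ratio_p_value`, `protein_diffs`, `k2p_to_reference`,
#'   `insertion_sites`, `verdict`
#' @export
screen_numt <- function(record, reference, frame = 0,
                        expected_ratio = c(5, 1, 18), p_cutoff = 0.01,
                        seq_id = "query") {
  rec <- if (length(record) == 1L) strsplit(toupper(record), "")[[1L]]
         else toupper(record)
  ref <- if (length(reference) == 1L) strsplit(toupper(reference), "")[[1L]]
         else toupper(reference)
  if (length(rec) != length(ref))
    stop("record and reference differ in aligned length")
  rec_gap <- rec == "-"; ref_gap <- ref == "-"
  has_indel <- any(xor(rec_gap, ref_gap))
  insertion_sites <- which(!rec_gap & ref_gap)
  # internal stops in the record's own degapped frame
  prot_rec <- translate_mt(rec, frame)
  aa <- strsplit(prot_rec, "")[[1L]]
  internal <- if (length(aa) > 1L) which(aa[-length(aa)] == "*")
              else integer(0)
  has_internal_stop <- length(internal) > 0L
  first_stop <- if (has_internal_stop) internal[1L] else NA_integer_
  # mismatches binned by codon position in reference coordinates
  ref_pos_index <- cumsum(!ref_gap)        # position along degapped reference
  valid <- !rec_gap & !ref_gap & rec %in% c("A", "C", "G", "T") &
           ref %in% c("A", "C", "G", "T") & ref_pos_index > frame
  mism <- valid & rec != ref
  cpos <- ((ref_pos_index - 1L - frame) %% 3L) + 1L
  codon_ratio <- vapply(1:3, function(p) sum(mism & cpos == p), 0L)
  # amino-acid differences over the reference's frame (record gaps -> N -> X)
  rec_on_ref <- rec[!ref_gap]
  rec_on_ref[rec_on_ref == "-"] <- "N"
  aa_ref <- strsplit(translate_mt(ref[!ref_gap], frame), "")[[1L]]
  aa_rec <- strsplit(translate_mt(rec_on_ref, frame), "")[[1L]]
  nn <- min(length(aa_ref), length(aa_rec))
  comp <- aa_ref[seq_len(nn)] != aa_rec[seq_len(nn)] &
          aa_ref[seq_len(nn)] != "X" & aa_rec[seq_len(nn)] != "X"
  protein_diffs <- sum(comp)
  d <- tryCatch(k2p(count_pair(rec, ref)), error = function(e) NA_real_)
  p_ratio <- exact_multinomial_test(codon_ratio, expected_ratio)
  verdict <- if (has_internal_stop || has_indel) "fail"
             else if (sum(codon_ratio) > 0 && p_ratio < p_cutoff) "suspect"
             else "pass"
  structure(list(seq_id = seq_id, frame_used = frame,
                 has_internal_stop = has_internal_stop,
                 first_stop_codon = first_stop, has_indel = has_indel,
                 codon_ratio = codon_ratio, ratio_p_value = p_ratio,
                 protein_diffs = protein_diffs, k2p_to_reference = d,
                 insertion_sites = insertion_sites, verdict = verdict),
            class = "numt_report")
}

#' @export
print.numt_report <- function(x, ...) {
  cat("numt_report [", x$seq_id, "] verdict:", x$verdict, "\n")
  cat("  internal stop:", x$has_internal_stop,
      if (x$has_internal_stop) paste0("(first at codon ", x$first_stop_codon,
                                      ")") else "", "\n")
  cat("  indel:", x$has_indel, " insertions at:",
      if (length(x$insertion_sites)) paste(x$insertion_sites, collapse = ",")
      else "none", "\n")
  cat("  codon-position mismatches", paste(x$codon_ratio, collapse = ":"),
      sprintf("(p=%.3g)", x$ratio_p_value), " protein diffs:",
      x$protein_diffs, "\n")
  invisible(x)
}

#' Screen every sequence of an alignment against a consensus reference
#'
#' @param aln a [barcode_alignment]
#' @param reference "consensus" (dataset-wide majority rule), "species"
#'   (within-species consensus, falling back to the dataset consensus for
#'   singletons), or an explicit seq_id
#' @param frame frame offset; `NULL` selects it with [choose_frame]
#' @param ... passed to [screen_numt]
#' @return data frame with one row per sequence: seq_id, verdict, flags,
#'   codon-position mismatch counts, p-value, protein diffs, K2P to
#'   reference
#' @export
screen_alignment <- function(aln, reference = "consensus", frame = NULL,
                             ...) {
  if (is.null(frame)) frame <- choose_frame(aln)
  ids <- rownames(aln$mat)
  if (identical(reference, "consensus")) {
    refs <- rep(consensus_sequence(aln), length(ids))
  } else if (identical(reference, "species")) {
    grouping <- setNames(aln$meta$species, aln$meta$seq_id)
    tab <- table(aln$meta$species)
    cons <- consensus_sequence(aln, grouping)
    fallback <- consensus_sequence(aln)
    refs <- ifelse(tab[grouping[ids]] >= 2L, cons[grouping[ids]], fallback)
  } else {
    if (!reference %in% ids) stop("reference seq_id not found: ", reference)
    refs <- rep(paste(aln$mat[reference, ], collapse = ""), length(ids))
  }
  rows <- lapply(seq_along(ids), function(i) {
    rep <- screen_numt(paste(aln$mat[i, ], collapse = ""), refs[i],
                       frame = frame, seq_id = ids[i], ...)
    data.frame(seq_id = rep$seq_id, frame_used = rep$frame_used,
               has_internal_stop = rep$has_internal_stop,
               first_stop_codon = rep$first_stop_codon,
               has_indel = rep$has_indel,
               n1 = rep$codon_ratio[1L], n2 = rep$codon_ratio[2L],
               n3 = rep$codon_ratio[3L], ratio_p_value = rep$ratio_p_value,
               protein_diffs = rep$protein_diffs,
               k2p_to_reference = rep$k2p_to_reference,
               verdict = rep$verdict, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Report insertion positions of a record relative to a reference
#'
#' Positions (1-based aligned columns) where the record carries a residue
#' against a reference gap — the signature of a numt insertion. Removing
#' the reported columns with [drop_columns] and re-screening is the
#' standard follow-up.
#'
#' @param record,reference aligned sequences of equal length
#' @return integer vector of 1-based aligned positions (empty when none)
#' @export
insertion_scan <- function(record, reference) {
  rec <- if (length(record) == 1L) strsplit(toupper(record), "")[[1L]]
         else toupper(record)
  ref <- if (length(reference) == 1L) strsplit(toupper(reference), "")[[1L]]
         else toupper(reference)
  if (length(rec) != length(ref))
    stop("record and reference differ in aligned length")
  which(rec != "-" & ref == "-")
}

#' Remove alignment columns from a sequence or alignment
#' @param x aligned sequence string or [barcode_alignment]
#' @param columns 1-based column indices to drop
#' @return same type as `x`
#' @export
drop_columns <- function(x, columns) {
  if (inherits(x, "barcode_alignment")) {
    x$mat <- x$mat[, -columns, drop = FALSE]
    return(x)
  }
  v <- strsplit(x, "")[[1L]]
  paste(v[-columns], collapse = "")
}

#' Divergence time of a nuclear pseudogene copy
#'
#' Linear two-rate clock: after the nuclear transfer the mitochondrial
#' lineage keeps evolving at `substitution_rate` while the numt evolves at
#' `pseudogene_rate`, so a K2P distance d between them accumulates at the
#' summed rate and \eqn{T = d / (r_{mt} + r_{numt})}. Rates are
#' substitutions/site/lineage per time unit and must be supplied; no
#' default rates are shipped.
#'
#' @param d K2P distance between pseudogene and functional copy (`NA`
#'   propagates)
#' @param substitution_rate functional mitochondrial rate (> 0)
#' @param pseudogene_rate post-transfer nuclear rate (> 0)
#' @return time since the nuclear transfer, in the unit of the rates
#' @export
divergence_time <- function(d, substitution_rate, pseudogene_rate) {
  stopifnot(substitution_rate > 0, pseudogene_rate > 0)
  d / (substitution_rate + pseudogene_rate)
}
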