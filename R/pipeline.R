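#' Configuration for a full barcoding analysis run
#'
#' @param input a [barcode_alignment], or path to an aligned FASTA
#' @param metadata optional path to a metadata TSV (see
#'   [read_metadata_tsv]) or a data frame
#' @param frame_offset 0:2, or `NULL` to auto-select with [choose_frame]
#' @param deletion "pairwise" or "complete" column deletion
#' @param bootstrap_B bootstrap replicates (0 disables the bootstrap stage
#'   and leaves the tree without supports)
#' @param seed RNG seed governing the bootstrap
#' @param thresholds a [barcode_thresholds]
#' @param exclusions taxa excluded from the gap pooling
#' @param collapse_subspecies collapse trinomials to binomials for pooling
#' @param keep_failed keep QC-failed sequences in the distance/tree stages
#'   (by default they are excluded, mirroring pseudogene removal)
#' @param outdir output directory for artifacts, or `NULL` to skip writing
#' @return list of class `run_config`
#' @export
run_config <- function(input, metadata = NULL, frame_offset = NULL,
                       deletion = "pairwise", bootstrap_B = 1000L,
                       seed = 1L, thresholds = barcode_thresholds(),
                       exclusions = character(),
                       collapse_subspecies = FALSE, keep_failed = FALSE,
                       outdir = NULL) {
  stopifnot(bootstrap_B >= 0L, inherits(thresholds, "barcode_thresholds"))
  structure(list(input = input, metadata = metadata,
                 frame_offset = frame_offset, deletion = deletion,
                 bootstrap_B = as.integer(bootstrap_B),
                 seed = as.integer(seed), thresholds = thresholds,
                 exclusions = exclusions,
                 collapse_subspecies = collapse_subspecies,
                 keep_failed = keep_failed, outdir = outdir),
            class = "run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg[setdiff(names(cfg), "input")]), tmp)
  unname(tools::md5sum(tmp))
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the complete barcoding analysis
#'
#' Orchestrates QC screening (failed sequences excluded from downstream
#' stages unless `keep_failed`), K2P total and transversion distance
#' matrices, the NJ tree with optional bootstrap supports, per-codon
#' composition, and the barcoding-gap summary with cryptic/synonymy flags.
#' When `outdir` is set, writes: distance matrices (PHYLIP + TSV), the
#' Newick tree, composition and QC TSV reports, the gap report JSON, a
#' summary JSON (sequence/species/genus counts, pool ranges, divergence
#' ratio, R-value, monophyly fraction, pseudogene count, config hash and
#' seed) and a MANIFEST. A stage failure aborts with the stage name; a
#' MANIFEST noting incompleteness is still written.
#'
#' @param cfg a [run_config]
#' @return invisible list with `alignment`, `qc`, `m_total`, `m_tv`,
#'   `tree`, `monophyly`, `composition`, `gap`, `flags`, `summary`
#' @export
run_barcodegap <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  artifacts <- character(0)
  stage <- "setup"
  result <- tryCatch({
    aln <- if (inherits(cfg$input, "barcode_alignment")) cfg$input
           else read_aligned_fasta(cfg$input)
    if (!is.null(cfg$metadata)) {
      tab <- if (is.data.frame(cfg$metadata)) cfg$metadata
             else read_metadata_tsv(cfg$metadata)
      aln <- attach_metadata(aln, tab)
    }
    if (is.null(cfg$frame_offset)) {
      aln$frame_offset <- choose_frame(aln)
      stage_log("setup", "auto-selected frame offset ", aln$frame_offset)
    } else aln$frame_offset <- cfg$frame_offset
    stage_log("setup", n_seq(aln), " sequences x ", aln_length(aln), " bp")

    stage <- "qc"
    qc <- screen_alignment(aln, frame = aln$frame_offset)
    failed <- qc$seq_id[qc$verdict == "fail"]
    stage_log("qc", length(failed), " of ", n_seq(aln),
              " sequences failed (pseudogene signatures)")
    aln_clean <- aln
    if (!cfg$keep_failed && length(failed)) {
      keep <- !rownames(aln$mat) %in% failed
      aln_clean$mat <- aln$mat[keep, , drop = FALSE]
      aln_clean$meta <- aln$meta[keep, , drop = FALSE]
    }

    stage <- "distances"
    counts <- pair_counts_matrix(aln_clean, cfg$deletion)
    m_total <- pairwise_matrix(aln_clean, "k2p_total", counts = counts)
    m_tv <- pairwise_matrix(aln_clean, "k2p_transversion", counts = counts)
    rv <- r_value(counts)
    stage_log("distances", length(m_total$labels), " taxa; ",
              sum(is.na(as.matrix(m_total)[upper.tri(as.matrix(m_total))])),
              " saturated pairs; R = ", round(as.numeric(rv), 3))

    stage <- "tree"
    if (cfg$bootstrap_B > 0L) {
      tree <- bootstrap_tree(aln_clean, "k2p_total", B = cfg$bootstrap_B,
                             seed = cfg$seed, deletion = cfg$deletion)
    } else {
      tree <- neighbor_joining(m_total)
    }
    species_of <- setNames(aln_clean$meta$species, aln_clean$meta$seq_id)
    if (cfg$collapse_subspecies)
      species_of <- setNames(collapse_subspecies(species_of),
                             names(species_of))
    mono <- species_monophyly(tree, species_of)
    stage_log("tree", sum(mono$monophyletic), " of ", nrow(mono),
              " species monophyletic")

    stage <- "composition"
    comp <- composition_profile(aln_clean, "dataset")

    stage <- "gap"
    gap <- gap_summary(m_total, m_tv, species_of, cfg$thresholds,
                       cfg$exclusions)
    flags <- flag_taxa(gap)
    stage_log("gap", nrow(flags$cryptic), " cryptic and ",
              nrow(flags$synonymy), " synonymy candidates")

    stage <- "summary"
    st <- gap$stats$k2p_total
    summary <- list(
      n_sequences = n_seq(aln_clean),
      n_species = length(unique(species_of)),
      n_genera = length(unique(aln_clean$meta$genus)),
      pool_ranges = lapply(seq_len(nrow(st)), function(i)
        list(pool = st$pool[i], n = st$n[i], min = st$min[i],
             max = st$max[i], mean = st$mean[i])),
      ratio_congeneric_over_conspecific =
        gap$ratio_congeneric_over_conspecific,
      r_value = as.numeric(rv),
      monophyly_fraction = mean(mono$monophyletic),
      pseudogene_count = length(failed),
      config_hash = config_hash(cfg),
      seed = cfg$seed)
    list(alignment = aln_clean, qc = qc, m_total = m_total, m_tv = m_tv,
         tree = tree, monophyly = mono, composition = comp, gap = gap,
         flags = flags, summary = summary)
  }, error = function(e) {
    if (!is.null(cfg$outdir)) {
      dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
      writeLines(c("INCOMPLETE RUN", paste("failed at stage:", stage),
                   paste("error:", conditionMessage(e)),
                   if (length(artifacts)) c("artifacts written:", artifacts)),
                 file.path(cfg$outdir, "MANIFEST"))
    }
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(cfg$outdir, f)
    write_distance_matrix(result$m_total, out("dist_k2p.phy"), "phylip")
    write_distance_matrix(result$m_total, out("dist_k2p.tsv"), "tsv")
    write_distance_matrix(result$m_tv, out("dist_tv.tsv"), "tsv")
    write_newick(result$tree, out("tree.nwk"))
    write_composition_tsv(result$composition, out("composition.tsv"))
    utils::write.table(result$qc, out("qc_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    gap_out <- list(thresholds = unclass(result$gap$thresholds),
                    stats = result$gap$stats,
                    ratio = result$gap$ratio_congeneric_over_conspecific,
                    pct_conspecific_below_theta =
                      result$gap$pct_conspecific_below_theta,
                    pct_congeneric_above_theta =
                      result$gap$pct_congeneric_above_theta,
                    cryptic = result$flags$cryptic,
                    synonymy = result$flags$synonymy,
                    schema_version = "1.0")
    jsonlite::write_json(gap_out, out("gap_report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    jsonlite::write_json(result$summary, out("summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts <- c("dist_k2p.phy", "dist_k2p.tsv", "dist_tv.tsv",
                   "tree.nwk", "composition.tsv", "qc_report.tsv",
                   "gap_report.json", "summary.json")
    writeLines(c("COMPLETE RUN",
                 paste("config hash:", result$summary$config_hash),
                 paste("seed:", cfg$seed), "artifacts:", artifacts),
               file.path(cfg$outdir, "MANIFEST"))
  }
  invisible(result)
}

#' Validate a run summary against the published schema
#'
#' The summary JSON schema (version 1.0) requires the fields
#' n_sequences, n_species, n_genera (integers), pool_ranges (array),
#' ratio_congeneric_over_conspecific, r_value, monophyly_fraction
#' (numbers), pseudogene_count (integer), config_hash (string) and seed
#' (integer).
#'
#' @param summary list as produced in `run_barcodegap()$summary`, or a
#'   path to a summary JSON file
#' @return TRUE invisibly; error describing the first violation otherwise
#' @export
validate_summary <- function(summary) {
  if (is.character(summary)) summary <- jsonlite::read_json(summary)
  need_num <- c("n_sequences", "n_species", "n_genera",
                "ratio_congeneric_over_conspecific", "r_value",
                "monophyly_fraction", "pseudogene_count", "seed")
  for (f in need_num) {
    if (is.null(summary[[f]])) stop("summary missing field: ", f)
    if (!is.numeric(summary[[f]]) || length(summary[[f]]) != 1L)
      stop("summary field not a scalar number: ", f)
  }
  if (!is.character(summary$config_hash)) stop("config_hash must be string")
  if (!is.list(summary$pool_ranges)) stop("pool_ranges must be an array")
  invisible(TRUE)
}
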