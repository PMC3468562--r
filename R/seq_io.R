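#' Construct a barcode alignment
#'
#' A `barcode_alignment` holds equal-length aligned nucleotide sequences
#' (typically ~650 bp COI barcode fragments) together with per-sequence
#' taxonomic metadata and the reading-frame offset of the first codon
#' position.
#'
#' @param sequences named character vector of aligned sequences (names are
#'   seq_ids), or a character matrix with one row per sequence and one
#'   aligned column per matrix column.
#' @param meta data frame with columns `seq_id`, `species`, `genus`, `site`,
#'   `accession`. Missing columns are filled with empty strings; `genus` is
#'   derived from the first token of `species` when absent.
#' @param frame_offset 0-based index of the alignment column holding the
#'   first codon position (0, 1 or 2).
#' @return An object of class `barcode_alignment` with elements `mat`
#'   (character matrix of upper-case single characters), `meta` and
#'   `frame_offset`.
#' @export
barcode_alignment <- function(sequences, meta = NULL, frame_offset = 0) {
  if (is.matrix(sequences)) {
    mat <- sequences
  } else {
    if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
      stop("sequences must be uniquely named")
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L) {
      bad <- names(sequences)[lens != lens[1L]][1L]
      stop("unaligned input: sequence '", bad, "' has length ",
           nchar(sequences[[bad]]), ", expected ", lens[1L])
    }
    mat <- do.call(rbind, strsplit(sequences, ""))
    rownames(mat) <- names(sequences)
  }
  mat[] <- toupper(mat)
  if (ncol(mat) < 1L) stop("alignment has zero columns")
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  ids <- rownames(mat)
  if (is.null(meta)) {
    meta <- data.frame(seq_id = ids, species = "", genus = "", site = "",
                       accession = "", stringsAsFactors = FALSE)
  } else {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    stopifnot("seq_id" %in% names(meta))
    for (col in c("species", "genus", "site", "accession"))
      if (!col %in% names(meta)) meta[[col]] <- ""
    meta <- meta[match(ids, meta$seq_id),
                 c("seq_id", "species", "genus", "site", "accession")]
    meta$seq_id <- ids
    for (col in c("species", "genus", "site", "accession"))
      meta[[col]][is.na(meta[[col]])] <- ""
  }
  fix <- meta$genus == "" & meta$species != ""
  meta$genus[fix] <- vapply(strsplit(meta$species[fix], "[ _]"),
                            `[`, "", 1L)
  rownames(meta) <- NULL
  structure(list(mat = mat, meta = meta, frame_offset = frame_offset),
            class = "barcode_alignment")
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat("barcode_alignment:", nrow(x$mat), "sequences x", ncol(x$mat),
      "columns (frame offset", x$frame_offset, ")\n")
  nsp <- length(unique(x$meta$species[x$meta$species != ""]))
  if (nsp) cat("  ", nsp, "species,",
               length(unique(x$meta$genus[x$meta$genus != ""])), "genera\n")
  invisible(x)
}

#' Number of sequences / alignment length
#' @param aln a `barcode_alignment`
#' @return integer count
#' @export
n_seq <- function(aln) nrow(aln$mat)

#' @rdname n_seq
#' @export
aln_length <- function(aln) ncol(aln$mat)

# Parse a "Genus_species|accession|site" FASTA header. Headers without '|'
# are taken verbatim as seq_id with empty metadata.
parse_header <- function(header) {
  parts <- strsplit(header, "|", fixed = TRUE)[[1L]]
  if (length(parts) == 1L)
    return(list(seq_id = header, species = "", accession = "", site = ""))
  species <- gsub("_", " ", parts[1L])
  accession <- if (length(parts) >= 2L) parts[2L] else ""
  site <- if (length(parts) >= 3L) parts[3L] else ""
  seq_id <- if (nzchar(accession)) accession else header
  list(seq_id = seq_id, species = species, accession = accession, site = site)
}

#' Read an aligned FASTA file of barcode sequences
#'
#' Headers in the dialect `Genus_species|accession|site` are parsed into
#' species, accession and site fields (the accession becomes the seq_id);
#' any other header is used verbatim as the seq_id. Sequences are
#' upper-cased. All sequences must have identical aligned length.
#'
#' @param path FASTA file path.
#' @param frame_offset 0-based column of the first codon position.
#' @return A [barcode_alignment].
#' @export
read_aligned_fasta <- function(path, frame_offset = 0) {
  seqs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                       forceDNAtolower = FALSE, whole.header = TRUE),
    error = function(e) stop("cannot read FASTA '", path, "': ",
                             conditionMessage(e)))
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  headers <- names(seqs)
  seqv <- toupper(vapply(seqs, as.character, ""))
  lens <- nchar(seqv)
  if (length(unique(lens)) != 1L) {
    bad <- headers[lens != stats::median(lens)][1L]
    stop("unaligned input: record '", bad, "' has length ",
         lens[headers == bad][1L], " while others have ",
         stats::median(lens))
  }
  info <- lapply(headers, parse_header)
  meta <- data.frame(
    seq_id = vapply(info, `[[`, "", "seq_id"),
    species = vapply(info, `[[`, "", "species"),
    genus = "",
    site = vapply(info, `[[`, "", "site"),
    accession = vapply(info, `[[`, "", "accession"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(meta$seq_id))
    stop("duplicate seq_id in FASTA: ",
         meta$seq_id[duplicated(meta$seq_id)][1L])
  names(seqv) <- meta$seq_id
  barcode_alignment(seqv, meta, frame_offset = frame_offset)
}

#' Write a barcode alignment to FASTA
#'
#' Headers are emitted in the `Genus_species|accession|site` dialect when
#' species metadata is present, otherwise as the bare seq_id.
#'
#' @param aln a [barcode_alignment]
#' @param path output file path
#' @export
write_aligned_fasta <- function(aln, path) {
  m <- aln$meta
  headers <- ifelse(
    m$species != "",
    paste(gsub(" ", "_", m$species), m$accession, m$site, sep = "|"),
    m$seq_id)
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  seqinr::write.fasta(as.list(seqs), names = headers, file.out = path,
                      nbchar = 80)
  invisible(path)
}

#' Attach or override sequence metadata from a table
#'
#' Rows are matched to alignment records by `seq_id` first, then by
#' `accession`. Matched rows override the species/genus/site/accession
#' fields that are non-empty in the table. Unmatched table rows are
#' reported with a warning and returned in the `unmatched` attribute.
#'
#' @param aln a [barcode_alignment]
#' @param table data frame with a `seq_id` and/or `accession` key column and
#'   any of `species`, `genus`, `site`, `accession`.
#' @return The updated alignment, with attribute `unmatched` listing keys of
#'   table rows that matched no record.
#' @export
attach_metadata <- function(aln, table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (!any(c("seq_id", "accession") %in% names(table)))
    stop("metadata table needs a seq_id or accession column")
  key <- if ("seq_id" %in% names(table)) table$seq_id else table$accession
  if (anyDuplicated(key[nzchar(key)]))
    stop("seq_id collision in metadata table: ",
         key[duplicated(key) & nzchar(key)][1L])
  meta <- aln$meta
  idx <- match(key, meta$seq_id)
  if ("accession" %in% names(table)) {
    miss <- is.na(idx)
    idx[miss] <- match(table$accession[miss], meta$accession)
  }
  unmatched <- key[is.na(idx)]
  if (length(unmatched))
    warning("metadata rows with no matching record: ",
            paste(unmatched, collapse = ", "))
  hit <- !is.na(idx)
  for (col in intersect(c("species", "genus", "site", "accession"),
                        names(table))) {
    val <- table[[col]][hit]
    use <- !is.na(val) & nzchar(val)
    meta[[col]][idx[hit][use]] <- val[use]
  }
  fix <- meta$genus == "" & meta$species != ""
  meta$genus[fix] <- vapply(strsplit(meta$species[fix], "[ _]"), `[`, "", 1L)
  aln$meta <- meta
  attr(aln, "unmatched") <- unmatched
  aln
}

#' Read a metadata TSV (columns seq_id, accession, species, genus, site)
#' @param path TSV file path
#' @return data frame
#' @export
read_metadata_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' Collapse trinomial (subspecies) names to binomials
#'
#' Subspecies such as the Culex pipiens complex can be treated either as
#' distinct terminal taxa or collapsed to the binomial for pooling.
#'
#' @param species character vector of species names
#' @return character vector with only the first two name tokens retained
#' @export
collapse_subspecies <- function(species) {
  vapply(strsplit(species, " +"), function(p)
    paste(p[seq_len(min(2L, length(p)))], collapse = " "), "")
}

#' Write a distance matrix (PHYLIP square or TSV)
#'
#' Labels containing whitespace are sanitized to underscores with a
#' warning. Undefined (saturated) entries are written as NA.
#'
#' @param m a [barcode_dist] or square numeric matrix with dimnames
#' @param path output file
#' @param dialect "phylip" (square, first line = taxon count) or "tsv"
#'   (header row of labels)
#' @export
write_distance_matrix <- function(m, path, dialect = c("phylip", "tsv")) {
  dialect <- match.arg(dialect)
  v <- as.matrix(m)
  labs <- rownames(v)
  if (any(grepl("[[:space:]]", labs))) {
    warning("labels containing whitespace sanitized to '_'")
    labs <- gsub("[[:space:]]+", "_", labs)
  }
  if (dialect == "phylip") {
    rows <- vapply(seq_len(nrow(v)), function(i)
      paste(c(labs[i], format(v[i, ], digits = 12, trim = TRUE,
                              scientific = FALSE)), collapse = " "), "")
    writeLines(c(as.character(nrow(v)), rows), path)
  } else {
    df <- as.data.frame(v)
    names(df) <- labs
    utils::write.table(cbind(seq_id = labs, df), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix]
#' @param path file path
#' @param dialect "phylip" or "tsv"
#' @param kind distance kind label to attach
#' @return a [barcode_dist]
#' @export
read_distance_matrix <- function(path, dialect = c("phylip", "tsv"),
                                 kind = "k2p_total") {
  dialect <- match.arg(dialect)
  if (dialect == "phylip") {
    lines <- readLines(path)
    n <- as.integer(lines[1L])
    toks <- strsplit(trimws(lines[2:(n + 1L)]), "[[:space:]]+")
    labs <- vapply(toks, `[`, "", 1L)
    v <- t(vapply(toks, function(x) as.numeric(x[-1L]), numeric(n)))
  } else {
    df <- utils::read.delim(path, check.names = FALSE)
    labs <- df[[1L]]
    v <- as.matrix(df[, -1L, drop = FALSE])
  }
  dimnames(v) <- list(labs, labs)
  barcode_dist(v, kind = kind)
}

#' Write a tree in Newick format
#'
#' Branch lengths are emitted; bootstrap supports (if present as node
#' labels) become internal-node labels.
#'
#' @param tree an `ape` \code{phylo} tree
#' @param path output file
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path file path
#' @return an `ape` \code{phylo}
#' @export
read_newick <- function(path) ape::read.tree(path)
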