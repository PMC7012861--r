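#' Load genome or contig sequences from a FASTA file
#'
#' Reads a (multi-record) FASTA file into a named [Biostrings::DNAStringSet].
#' Sequence identifiers are taken as the first whitespace-delimited token of
#' each header and must be unique; sequences are uppercased on input. IUPAC
#' ambiguity letters (including `N`) are retained — the HSE scanner treats
#' them conservatively (see [scan_sequence()]).
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`, one element per contig.
#' @seealso [load_genes()], [extract_upstream()]
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgtACGT"), fa)
#' load_genome(fa)
load_genome <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    abort_hseprom("hseprom_missing_file",
                  sprintf("genome FASTA not found: %s", path))
  seqs <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path),
      error = function(e) abort_hseprom(
        "hseprom_invalid_sequence",
        sprintf("could not parse '%s' as nucleotide FASTA: %s",
                path, conditionMessage(e)))
    ),
    # Biostrings silently drops non-IUPAC letters with a warning; treat
    # them as a hard error so coordinates cannot shift
    warning = function(w) {
      if (grepl("invalid one-letter sequence", conditionMessage(w)))
        abort_hseprom("hseprom_invalid_sequence",
                      sprintf("non-IUPAC letter(s) in '%s'", path))
      invokeRestart("muffleWarning")
    }
  )
  if (length(seqs) == 0L)
    abort_hseprom("hseprom_empty_input",
                  sprintf("FASTA file '%s' contains no records", path))
  if (any(Biostrings::width(seqs) == 0L))
    abort_hseprom("hseprom_empty_input",
                  sprintf("FASTA file '%s' contains an empty sequence", path))
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    abort_hseprom("hseprom_duplicate_id",
                  sprintf("duplicate contig id(s): %s",
                          paste(unique(dup), collapse = ", ")))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(seqs) <- ids
  seqs
}

#' Load gene models (ATG anchor and strand) from GFF3 or BED
#'
#' Reduces each feature to the single coordinate the promoter extractor
#' needs: the position of the `A` of the start codon on the forward strand
#' of its contig. For GFF3 (1-based inclusive) that is the feature start on
#' `+` and the feature end on `-`; BED input (0-based half-open) is
#' converted so that `atg_pos = start + 1` on `+` and `atg_pos = end` on
#' `-`.
#'
#' @param path Path to a GFF3 or BED6 file.
#' @param dialect Either `"gff3"` or `"bed"`.
#' @return A data frame with columns `gene_id`, `contig_id`, `atg_pos`
#'   (1-based forward-strand coordinate) and `strand` (`"+"` or `"-"`).
#' @export
load_genes <- function(path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    abort_hseprom("hseprom_missing_file",
                  sprintf("gene model file not found: %s", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = dialect),
    error = function(e) abort_hseprom(
      "hseprom_parse_error",
      sprintf("could not parse '%s' as %s: %s",
              path, dialect, conditionMessage(e)))
  )
  if (length(gr) == 0L)
    abort_hseprom("hseprom_empty_input",
                  sprintf("'%s' contains no features", path))
  str <- as.character(GenomicRanges::strand(gr))
  if (any(!str %in% c("+", "-")))
    abort_hseprom("hseprom_unknown_strand",
                  sprintf("feature(s) with unknown strand symbol in '%s'; %s",
                          path, "each gene must be '+' or '-'"))
  mc <- S4Vectors::mcols(gr)
  gene_id <- if (dialect == "bed") {
    as.character(mc$name)
  } else if (!is.null(mc$ID)) {
    as.character(mc$ID)
  } else if (!is.null(mc$Name)) {
    as.character(mc$Name)
  } else {
    NULL
  }
  if (is.null(gene_id) || anyNA(gene_id))
    abort_hseprom("hseprom_parse_error",
                  sprintf("feature(s) in '%s' lack a gene identifier", path))
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup))
    abort_hseprom("hseprom_duplicate_id",
                  sprintf("duplicate gene id(s): %s",
                          paste(unique(dup), collapse = ", ")))
  # rtracklayer returns 1-based inclusive GRanges for both dialects, so the
  # BED 0-based -> 1-based conversion is already applied.
  atg_pos <- ifelse(str == "+",
                    GenomicRanges::start(gr),
                    GenomicRanges::end(gr))
  data.frame(
    gene_id = gene_id,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    atg_pos = as.integer(atg_pos),
    strand = str,
    stringsAsFactors = FALSE
  )
}

#' Extract the upstream promoter region of one gene
#'
#' Returns the `window` bases immediately 5' of the ATG, in gene
#' orientation: the last base of the returned sequence is the base at
#' offset -1 relative to the `A` of the start codon (the ATG itself is
#' excluded), the first base is at offset `-actual_length`. On the `-`
#' strand the forward-strand span is reverse-complemented. Windows running
#' off the contig end are truncated with a warning, not an error, since
#' draft contigs routinely clip upstream regions.
#'
#' @param genome A named `DNAStringSet` as returned by [load_genome()].
#' @param gene A one-row data frame (or list) with fields `gene_id`,
#'   `contig_id`, `atg_pos`, `strand`, as returned by [load_genes()].
#' @param window Upstream window length in nt (default 2000, i.e. the
#'   2-kb putative promoter region).
#' @return A one-row data frame with columns `gene_id`, `sequence`,
#'   `requested_length`, `actual_length`, `truncated`, `contig_id`,
#'   `span_start`, `span_end` (1-based inclusive forward-strand interval)
#'   and `strand`.
#' @export
extract_upstream <- function(genome, gene, window = 2000L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L)
    abort_hseprom("hseprom_bad_window", "window must be >= 1 nt")
  gene_id <- as.character(gene$gene_id)
  contig_id <- as.character(gene$contig_id)
  atg_pos <- as.integer(gene$atg_pos)
  strand <- as.character(gene$strand)
  if (!contig_id %in% names(genome))
    abort_hseprom("hseprom_unknown_contig",
                  sprintf("gene %s: contig '%s' not in genome",
                          gene_id, contig_id))
  if (!strand %in% c("+", "-"))
    abort_hseprom("hseprom_unknown_strand",
                  sprintf("gene %s: unknown strand '%s'", gene_id, strand))
  L <- length(genome[[contig_id]])
  if (is.na(atg_pos) || atg_pos < 1L || atg_pos > L)
    abort_hseprom("hseprom_coordinate_out_of_range",
                  sprintf("gene %s: atg_pos %d outside contig '%s' (1..%d)",
                          gene_id, atg_pos, contig_id, L))
  if (strand == "+") {
    span_start <- max(1L, atg_pos - window)
    span_end <- atg_pos - 1L
  } else {
    span_start <- atg_pos + 1L
    span_end <- min(L, atg_pos + window)
  }
  if (span_end < span_start)
    abort_hseprom("hseprom_empty_promoter",
                  sprintf("gene %s: no upstream sequence (ATG at contig edge)",
                          gene_id))
  seq <- Biostrings::subseq(genome[[contig_id]], span_start, span_end)
  if (strand == "-")
    seq <- Biostrings::reverseComplement(seq)
  actual <- span_end - span_start + 1L
  truncated <- actual < window
  if (truncated)
    warning(sprintf("gene %s: upstream window truncated to %d nt by contig end",
                    gene_id, actual), call. = FALSE)
  data.frame(
    gene_id = gene_id,
    sequence = as.character(seq),
    requested_length = window,
    actual_length = actual,
    truncated = truncated,
    contig_id = contig_id,
    span_start = span_start,
    span_end = span_end,
    strand = strand,
    stringsAsFactors = FALSE
  )
}

#' Extract upstream regions for a table of genes
#'
#' Vectorised wrapper around [extract_upstream()].
#'
#' @inheritParams extract_upstream
#' @param genes Data frame of gene models from [load_genes()].
#' @return A data frame with one row per gene (see [extract_upstream()]).
#' @export
extract_promoters <- function(genome, genes, window = 2000L) {
  rows <- lapply(seq_len(nrow(genes)),
                 function(i) extract_upstream(genome, genes[i, ], window))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write promoter records to FASTA
#'
#' Headers follow `gene_id|contig:start-end|strand|len`, carrying the
#' provenance coordinates so matches can be mapped back to the contig.
#'
#' @param promoters Promoter data frame from [extract_promoters()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(promoters, path) {
  seqs <- Biostrings::DNAStringSet(promoters$sequence)
  names(seqs) <- sprintf("%s|%s:%d-%d|%s|%d",
                         promoters$gene_id, promoters$contig_id,
                         promoters$span_start, promoters$span_end,
                         promoters$strand, promoters$actual_length)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read promoter records written by [write_promoters()]
#'
#' @param path FASTA path with `gene_id|contig:start-end|strand|len` headers.
#' @return A promoter data frame; `requested_length` is not recorded in the
#'   FASTA header and is set to `actual_length`, with `truncated = NA`.
#' @export
read_promoters <- function(path) {
  seqs <- load_genome(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) != 4L))
    abort_hseprom("hseprom_parse_error",
                  "promoter FASTA headers must be gene_id|contig:span|strand|len")
  span <- t(vapply(parts, function(p) {
    m <- regmatches(p[2], regexec("^(.*):([0-9]+)-([0-9]+)$", p[2]))[[1]]
    if (length(m) != 4L)
      abort_hseprom("hseprom_parse_error",
                    sprintf("bad span field in header: %s", p[2]))
    m[2:4]
  }, character(3)))
  out <- data.frame(
    gene_id = vapply(parts, `[`, "", 1L),
    sequence = as.character(seqs),
    requested_length = NA_integer_,
    actual_length = Biostrings::width(seqs),
    truncated = NA,
    contig_id = span[, 1],
    span_start = as.integer(span[, 2]),
    span_end = as.integer(span[, 3]),
    strand = vapply(parts, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
  out$requested_length <- out$actual_length
  out
}
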