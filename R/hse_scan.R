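#' Built-in heat-shock element consensus patterns
#'
#' The three 15-bp HSE geometries distinguished by the relative orientation
#' and spacing of their nGAAn/nTTCn units, as bound by heat-shock factor:
#' tail-tail (`NTTCNNGAANNNNNN`), head-head (`NGAANNTCCNNNNNN`) and
#' step/gap (`NTTCNNNNNNNTTCN`). `N` matches any nucleotide.
#'
#' @return A data frame with columns `name` and `consensus` (15 characters
#'   over `A`, `C`, `G`, `T`, `N`).
#' @export
#' @examples
#' hse_patterns()
hse_patterns <- function() {
  data.frame(
    name = c("tail_tail", "head_head", "step_gap"),
    consensus = c("NTTCNNGAANNNNNN", "NGAANNTCCNNNNNN", "NTTCNNNNNNNTTCN"),
    stringsAsFactors = FALSE
  )
}

validate_patterns <- function(patterns) {
  if (!is.data.frame(patterns) || nrow(patterns) == 0L)
    abort_hseprom("hseprom_empty_patterns", "pattern set must be non-empty")
  if (!all(c("name", "consensus") %in% names(patterns)))
    abort_hseprom("hseprom_bad_pattern",
                  "patterns need 'name' and 'consensus' columns")
  cons <- toupper(patterns$consensus)
  if (any(nchar(cons) != 15L))
    abort_hseprom("hseprom_bad_pattern",
                  "every HSE consensus must be exactly 15 characters")
  if (any(!strsplit(paste(cons, collapse = ""), "")[[1]] %in%
          c("A", "C", "G", "T", "N")))
    abort_hseprom("hseprom_bad_pattern",
                  "consensus letters must be A, C, G, T or N")
  if (anyDuplicated(patterns$name))
    abort_hseprom("hseprom_duplicate_id", "pattern names must be unique")
  patterns$consensus <- cons
  patterns
}

#' Read user-defined HSE patterns from a two-column TSV
#'
#' @param path TSV with columns `name` and `consensus15` (no header
#'   required; a header line is auto-detected).
#' @return A validated pattern data frame usable wherever [hse_patterns()]
#'   is.
#' @export
read_patterns <- function(path) {
  if (!file.exists(path))
    abort_hseprom("hseprom_missing_file",
                  sprintf("pattern file not found: %s", path))
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2L)
    abort_hseprom("hseprom_parse_error",
                  "pattern file must have two tab-separated columns")
  if (identical(tolower(tab[1, 1]), "name")) tab <- tab[-1, , drop = FALSE]
  validate_patterns(data.frame(name = tab[, 1], consensus = tab[, 2],
                               stringsAsFactors = FALSE))
}

#' Test one 15-nt window against one HSE consensus
#'
#' A window matches iff every fixed (A/C/G/T) consensus position holds that
#' exact letter; `N` consensus positions match any letter. Ambiguity
#' letters in the window (including `N`) therefore match consensus `N` but
#' never a fixed letter — an unknown base cannot be asserted to equal a
#' specific one.
#'
#' @param window_seq A 15-character nucleotide string.
#' @param pattern A one-row pattern data frame (or list) with a
#'   `consensus` field, e.g. one row of [hse_patterns()].
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' match_window("ATTCGGGAAACGTAC", hse_patterns()[1, ])
match_window <- function(window_seq, pattern) {
  window_seq <- toupper(window_seq)
  if (nchar(window_seq) != 15L)
    abort_hseprom("hseprom_bad_window", "window must be exactly 15 nt")
  cons <- strsplit(toupper(pattern$consensus), "")[[1]]
  win <- strsplit(window_seq, "")[[1]]
  all(cons == "N" | cons == win)
}

# Vectorised scan of one character vector against one consensus: returns
# 1-based start positions of matching 15-nt windows.
scan_chars <- function(chars, consensus) {
  w <- 15L
  L <- length(chars)
  if (L < w) return(integer(0))
  n_win <- L - w + 1L
  cons <- strsplit(consensus, "")[[1]]
  ok <- rep(TRUE, n_win)
  for (j in which(cons != "N")) {
    ok <- ok & (chars[j:(j + n_win - 1L)] == cons[j])
    if (!any(ok)) return(integer(0))
  }
  which(ok)
}

#' Scan a promoter for HSE consensus matches
#'
#' Slides a 15-nt window over the promoter and reports every
#' (offset, pattern) hit. Overlapping hits are all kept, and a window
#' matching k patterns yields k matches — no deduplication, so per-type
#' counts are reproducible without reference to any merging rule. Offsets
#' are relative to the ATG: the base immediately 5' of the start codon is
#' offset -1, so a match's `start_offset` is always <= -15. Only complete
#' 15-nt windows are considered.
#'
#' By default only the sense (promoter-orientation) strand is scanned: the
#' HSE pattern set already encodes the inverted-repeat geometry of the
#' nGAAn units. With `both_strands = TRUE` the reverse complement is
#' scanned too and its hits reported at the mirrored sense offset with
#' `strand_scanned = "antisense"` (`window_seq` then holds the antisense
#' sequence that matched).
#'
#' @param promoter A one-row promoter data frame from [extract_upstream()]
#'   (fields `gene_id`, `sequence`), or a bare list with those fields.
#' @param patterns Pattern data frame (default the three built-ins).
#' @param both_strands Also scan the reverse complement (default `FALSE`).
#' @return A data frame of matches: `gene_id`, `pattern_name`,
#'   `start_offset`, `window_seq`, `strand_scanned`, ordered by
#'   `start_offset` then pattern name. Promoters shorter than 15 nt yield
#'   zero rows.
#' @export
scan_sequence <- function(promoter, patterns = hse_patterns(),
                          both_strands = FALSE) {
  patterns <- validate_patterns(patterns)
  gene_id <- as.character(promoter$gene_id)
  seq <- toupper(as.character(promoter$sequence))
  L <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  res <- list()
  for (k in seq_len(nrow(patterns))) {
    pos <- scan_chars(chars, patterns$consensus[k])
    if (length(pos))
      res[[length(res) + 1L]] <- data.frame(
        gene_id = gene_id,
        pattern_name = patterns$name[k],
        start_offset = pos - L - 1L,
        window_seq = substring(seq, pos, pos + 14L),
        strand_scanned = "sense",
        stringsAsFactors = FALSE
      )
  }
  if (isTRUE(both_strands)) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    rc_chars <- strsplit(rc, "")[[1]]
    for (k in seq_len(nrow(patterns))) {
      pos <- scan_chars(rc_chars, patterns$consensus[k])
      if (length(pos))
        res[[length(res) + 1L]] <- data.frame(
          gene_id = gene_id,
          pattern_name = patterns$name[k],
          # antisense window at revcomp position j covers sense positions
          # (L-j-13)..(L-j+1); its mirrored sense start offset is -(j+14)
          start_offset = -(pos + 14L),
          window_seq = substring(rc, pos, pos + 14L),
          strand_scanned = "antisense",
          stringsAsFactors = FALSE
        )
    }
  }
  out <- if (length(res)) do.call(rbind, res) else empty_matches()
  out <- out[order(out$start_offset, out$pattern_name, out$strand_scanned), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_matches <- function() {
  data.frame(gene_id = character(), pattern_name = character(),
             start_offset = integer(), window_seq = character(),
             strand_scanned = character(), stringsAsFactors = FALSE)
}

#' Scan every promoter in a table
#'
#' @inheritParams scan_sequence
#' @param promoters Promoter data frame from [extract_promoters()].
#' @return Combined match data frame across genes.
#' @export
scan_promoters <- function(promoters, patterns = hse_patterns(),
                           both_strands = FALSE) {
  out <- lapply(seq_len(nrow(promoters)), function(i)
    scan_sequence(promoters[i, ], patterns, both_strands))
  out <- do.call(rbind, c(list(empty_matches()), out))
  rownames(out) <- NULL
  out
}

#' Count HSE matches per type for one gene
#'
#' Produces the per-gene row of the per-type HSE count table: tail-tail,
#' head-head and step/gap counts and their total.
#'
#' @param matches Match data frame for a single gene (possibly empty).
#' @param gene_id The gene the matches belong to.
#' @return One-row data frame `gene_id`, `n_tail_tail`, `n_head_head`,
#'   `n_step_gap`, `n_total`.
#' @export
count_by_type <- function(matches, gene_id) {
  if (nrow(matches) && any(matches$gene_id != gene_id))
    abort_hseprom("hseprom_mixed_genes",
                  "matches from more than one gene passed to count_by_type")
  types <- hse_patterns()$name
  unknown <- setdiff(unique(matches$pattern_name), types)
  if (length(unknown))
    abort_hseprom("hseprom_bad_pattern",
                  sprintf("non-canonical pattern name(s) in matches: %s",
                          paste(unknown, collapse = ", ")))
  n <- vapply(types, function(t) sum(matches$pattern_name == t), 0L)
  data.frame(gene_id = gene_id,
             n_tail_tail = n[["tail_tail"]],
             n_head_head = n[["head_head"]],
             n_step_gap = n[["step_gap"]],
             n_total = sum(n),
             stringsAsFactors = FALSE)
}

#' Per-gene HSE count table
#'
#' One row per gene (zero counts for genes without matches), sorted by
#' `gene_id`.
#'
#' @param matches Combined match data frame from [scan_promoters()].
#' @param gene_ids Genes to report; defaults to the genes present in
#'   `matches`.
#' @return Data frame of [count_by_type()] rows.
#' @export
hse_count_table <- function(matches, gene_ids = unique(matches$gene_id)) {
  gene_ids <- sort(unique(as.character(gene_ids)))
  out <- do.call(rbind, lapply(gene_ids, function(g)
    count_by_type(matches[matches$gene_id == g, , drop = FALSE], g)))
  if (is.null(out))
    out <- count_by_type(empty_matches(), character(0))[0, ]
  rownames(out) <- NULL
  out
}

#' Naive reference scanner (test oracle)
#'
#' Re-implements the scanning contract of [scan_sequence()] by the most
#' direct means possible: an explicit loop over every window position and
#' every consensus letter, sharing no code with the production scanner.
#' Used in the test suite as an independent verification path; sense
#' strand only.
#'
#' @param sequence A nucleotide string.
#' @param patterns Pattern data frame.
#' @return Match data frame (without `gene_id`): `pattern_name`,
#'   `start_offset`, `window_seq`, ordered like [scan_sequence()].
#' @export
brute_force_oracle <- function(sequence, patterns = hse_patterns()) {
  sequence <- toupper(as.character(sequence))
  L <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  cons_list <- lapply(patterns$consensus, function(p) strsplit(p, "")[[1]])
  hit_name <- character(0)
  hit_pos <- integer(0)
  if (L >= 15L) {
    for (i in 1:(L - 14L)) {
      for (k in seq_along(cons_list)) {
        cons <- cons_list[[k]]
        ok <- TRUE
        for (j in 1:15) {
          cj <- cons[j]
          if (cj != "N" && chars[i + j - 1L] != cj) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          hit_name <- c(hit_name, patterns$name[k])
          hit_pos <- c(hit_pos, i)
        }
      }
    }
  }
  wins <- if (length(hit_pos)) substring(sequence, hit_pos, hit_pos + 14L)
          else character(0)
  out <- data.frame(pattern_name = hit_name,
                    start_offset = hit_pos - L - 1L,
                    window_seq = wins,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start_offset, out$pattern_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write HSE matches as BED6 on the contig forward strand
#'
#' Each match window is mapped back through the promoter's contig span to
#' a 0-based half-open interval on the forward strand; `name` is the
#' pattern name, `score` 0, `strand` the gene's strand.
#'
#' @param matches Match data frame from [scan_promoters()].
#' @param promoters Promoter data frame the matches came from.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_matches_bed <- function(matches, promoters, path) {
  idx <- match(matches$gene_id, promoters$gene_id)
  if (anyNA(idx))
    abort_hseprom("hseprom_unknown_contig",
                  "matches refer to gene(s) absent from the promoter table")
  Lp <- promoters$actual_length[idx]
  # promoter-internal 1-based start of the window, in gene orientation
  i <- matches$start_offset + Lp + 1L
  plus <- promoters$strand[idx] == "+"
  bed_start <- ifelse(plus,
                      promoters$span_start[idx] + i - 1L - 1L,
                      promoters$span_end[idx] - i - 14L)
  bed <- data.frame(chrom = promoters$contig_id[idx],
                    start = bed_start,
                    end = bed_start + 15L,
                    name = matches$pattern_name,
                    score = 0L,
                    strand = promoters$strand[idx],
                    stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the per-gene HSE count table as TSV
#'
#' Header `gene_id  tail_tail  head_head  step_gap  total`, one row per
#' gene, sorted by `gene_id`.
#'
#' @param counts Count table from [hse_count_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  out <- counts[order(counts$gene_id), , drop = FALSE]
  names(out) <- c("gene_id", "tail_tail", "head_head", "step_gap", "total")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
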