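#' Cluster HSE matches along a promoter
#'
#' Single-linkage chaining of matches by start offset: a match joins the
#' current cluster iff its `start_offset` minus the previous match's
#' `start_offset` is at most `max_gap`. All pattern types are pooled.
#' Clusters are reported 5' to 3' (most distal first).
#'
#' @param matches Match data frame for a single gene.
#' @param max_gap Maximum spacing (nt) between consecutive match starts
#'   within one cluster (default 50).
#' @return Data frame `gene_id`, `cluster_index`, `size`, `span_start`,
#'   `span_end` (offsets relative to the ATG; `span_end` is the last base
#'   of the most proximal member window, i.e. max offset + 14), with the
#'   member start offsets in a list column `member_offsets`.
#' @export
cluster_matches <- function(matches, max_gap = 50L) {
  if (max_gap < 0)
    abort_hseprom("hseprom_bad_parameter", "max_gap must be non-negative")
  if (nrow(matches) == 0L)
    return(data.frame(gene_id = character(), cluster_index = integer(),
                      size = integer(), span_start = integer(),
                      span_end = integer(), stringsAsFactors = FALSE))
  gene <- unique(matches$gene_id)
  if (length(gene) > 1L)
    abort_hseprom("hseprom_mixed_genes",
                  "cluster_matches expects matches from a single gene")
  off <- sort(matches$start_offset)
  brk <- c(TRUE, diff(off) > max_gap)
  idx <- cumsum(brk)
  out <- do.call(rbind, lapply(unique(idx), function(k) {
    mem <- off[idx == k]
    data.frame(gene_id = gene, cluster_index = k, size = length(mem),
               span_start = min(mem), span_end = max(mem) + 14L,
               stringsAsFactors = FALSE)
  }))
  out$member_offsets <- split(off, idx)
  rownames(out) <- NULL
  out
}

#' Select the minimal promoter fragment harbouring most HSEs
#'
#' Finds the smallest fragment length `L` such that the windows of at
#' least `ceiling(min_fraction * n)` of the gene's `n` matches lie
#' entirely within `[-L, -1]` — an explicit, overridable surrogate for
#' choosing the upstream fragment "harbouring most of the HSEs" when
#' designing reporter constructs. A promoter without any match returns the
#' full promoter, flagged.
#'
#' @param promoter One-row promoter data frame.
#' @param matches Match data frame for that gene.
#' @param min_fraction Minimum fraction of matches the fragment must
#'   contain (default 0.8).
#' @return One-row data frame `gene_id`, `fragment_length`,
#'   `hse_contained`, `hse_total`, `coverage`, `no_hse`.
#' @export
select_fragment <- function(promoter, matches, min_fraction = 0.8) {
  if (!(min_fraction > 0 && min_fraction <= 1))
    abort_hseprom("hseprom_bad_parameter",
                  "min_fraction must be in (0, 1]")
  gene_id <- as.character(promoter$gene_id)
  n <- nrow(matches)
  if (n == 0L) {
    warning(sprintf("gene %s: no HSE matches; returning full promoter",
                    gene_id), call. = FALSE)
    return(data.frame(gene_id = gene_id,
                      fragment_length = promoter$actual_length,
                      hse_contained = 0L, hse_total = 0L,
                      coverage = 1.0, no_hse = TRUE,
                      stringsAsFactors = FALSE))
  }
  if (any(matches$gene_id != gene_id))
    abort_hseprom("hseprom_mixed_genes",
                  "matches do not belong to the given promoter")
  k <- ceiling(min_fraction * n)
  # a match at start_offset s lies inside [-L, -1] iff s >= -L;
  # the k most ATG-proximal matches fix the minimal L
  s_desc <- sort(matches$start_offset, decreasing = TRUE)
  L <- -s_desc[k]
  contained <- sum(matches$start_offset >= -L)
  data.frame(gene_id = gene_id, fragment_length = as.integer(L),
             hse_contained = as.integer(contained), hse_total = n,
             coverage = contained / n, no_hse = FALSE,
             stringsAsFactors = FALSE)
}

#' Rank promoters by total HSE count
#'
#' Descending by `n_total`; ties broken by `gene_id` ascending, so the
#' ordering is deterministic.
#'
#' @param rows Count table from [hse_count_table()].
#' @return The same rows, reordered.
#' @export
rank_promoters <- function(rows) {
  out <- rows[order(-rows$n_total, rows$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the cluster report as TSV
#'
#' Columns `gene_id  cluster_index  size  span_start  span_end`, offsets
#' relative to the ATG (negative integers).
#'
#' @param clusters Cluster data frame from [cluster_matches()] (one or
#'   several genes rbind-ed).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(clusters, path) {
  cols <- c("gene_id", "cluster_index", "size", "span_start", "span_end")
  write.table(clusters[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the fragment-selection report as TSV
#'
#' Columns `gene_id  fragment_length  hse_contained  hse_total  coverage`.
#'
#' @param fragments Fragment rows from [select_fragment()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fragment_tsv <- function(fragments, path) {
  cols <- c("gene_id", "fragment_length", "hse_contained", "hse_total",
            "coverage")
  write.table(fragments[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
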