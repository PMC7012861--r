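tt_pat <- hse_patterns()[1, ]
hh_pat <- hse_patterns()[2, ]
sg_pat <- hse_patterns()[3, ]

test_that("match_window honours fixed letters and treats N as wildcard", {
  expect_true(match_window("ATTCGGGAAACGTAC", tt_pat))
  expect_true(match_window("CGAAGGTCCTTTTTT", hh_pat))
  expect_true(match_window("GTTCAAAAAAATTCA", sg_pat))
  for (p in list(tt_pat, hh_pat, sg_pat))
    expect_false(match_window("AAAAAAAAAAAAAAA", p))
  # sequence ambiguity letters match consensus N but never fixed letters
  expect_false(match_window("ANNNNNNNNNNNNNN", tt_pat))
  expect_true(match_window("NTTCNNGAANNNNNN", tt_pat))
  expect_error(match_window("ACGT", tt_pat), class = "hseprom_bad_window")
})

test_that("pattern self-consistency: consensus with N set to C matches itself", {
  for (i in 1:3) {
    p <- hse_patterns()[i, ]
    win <- gsub("N", "C", p$consensus)
    expect_true(match_window(win, p))
  }
})

test_that("scan_sequence finds a single planted motif and nothing else", {
  s <- paste0(strrep("G", 20), "ATTCGGGAAACGTAC", strrep("G", 15))
  m <- scan_sequence(as_promoter(s))
  expect_equal(nrow(m), 1L)
  expect_equal(m$pattern_name, "tail_tail")
  expect_equal(m$start_offset, -30L)
  expect_equal(m$window_seq, "ATTCGGGAAACGTAC")
  expect_scan_equals_oracle(s)

  expect_equal(nrow(scan_sequence(as_promoter(strrep("A", 2000)))), 0L)
  # promoters shorter than one window yield an empty result, not an error
  expect_equal(nrow(scan_sequence(as_promoter("ACGT"))), 0L)
  expect_error(scan_sequence(as_promoter("ACGT"), patterns = hse_patterns()[0, ]),
               class = "hseprom_empty_patterns")
})

test_that("a window matching two pattern types is counted once per type", {
  m <- scan_sequence(as_promoter("ATTCGGGAAGATTCA"))
  expect_equal(nrow(m), 2L)
  expect_equal(sort(m$pattern_name), c("step_gap", "tail_tail"))
  expect_equal(unique(m$start_offset), -15L)
  row <- count_by_type(m, "g1")
  expect_equal(unname(unlist(row[, -1])), c(1L, 0L, 1L, 2L))
})

test_that("count_by_type tallies per type and guards gene identity", {
  empty <- count_by_type(scan_sequence(as_promoter(strrep("C", 100))), "gX")
  expect_equal(unname(unlist(empty[, -1])), c(0L, 0L, 0L, 0L))
  m <- scan_sequence(as_promoter("ATTCGGGAAGATTCA", gene_id = "gA"))
  expect_error(count_by_type(m, "gB"), class = "hseprom_mixed_genes")
})

test_that("scanner agrees with the naive oracle on random sequences", {
  set.seed(101)
  for (i in 1:100) expect_scan_equals_oracle(rand_seq(500))
  # all-N input: N never matches a fixed consensus letter, so zero matches
  expect_scan_equals_oracle(strrep("N", 200))
  expect_equal(nrow(scan_sequence(as_promoter(strrep("N", 200)))), 0L)
})

test_that("planted motifs at both promoter boundaries are recovered", {
  motif <- "ATTCGGGAAACGTAC"  # tail_tail
  s <- paste0(motif, strrep("C", 2000 - 30), motif)
  expect_equal(nchar(s), 2000L)
  m <- scan_sequence(as_promoter(s))
  expect_equal(m$start_offset, c(-2000L, -15L))
  expect_equal(m$pattern_name, rep("tail_tail", 2))
  expect_scan_equals_oracle(s)
})

test_that("count additivity under a neutral guard and monotone planting", {
  set.seed(202)
  for (i in 1:10) {
    a <- rand_seq(300)
    b <- rand_seq(300)
    joined <- paste0(a, strrep("C", 14), b)
    na <- nrow(brute_force_oracle(a))
    nb <- nrow(brute_force_oracle(b))
    nj <- nrow(brute_force_oracle(joined))
    expect_gte(nj, na + nb)
    # junction-spanning windows are the only possible excess; windows fully
    # inside a or b must contribute exactly na + nb
    hits <- brute_force_oracle(joined)
    pos <- hits$start_offset + nchar(joined) + 1L  # 1-based window start
    junction <- pos > nchar(a) - 14L & pos <= nchar(a) + 14L
    expect_equal(nj, na + nb + sum(junction))
  }
  # planting one extra non-overlapping motif raises exactly one type by one
  spacer <- strrep("G", 400)
  base <- scan_sequence(as_promoter(spacer))
  expect_equal(nrow(base), 0L)
  planted <- paste0(strrep("G", 100), "CGAACCTCCGCGCGC", strrep("G", 285))
  m <- count_by_type(scan_sequence(as_promoter(planted)), "g1")
  expect_equal(unname(unlist(m[, -1])), c(0L, 1L, 0L, 1L))
})

test_that("antisense scanning reports mirrored sense offsets", {
  # head_head on the antisense strand of a C/G background
  motif <- "CGAACCTCCGCGCGC"
  rc_motif <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(motif)))
  s <- paste0(strrep("C", 50), rc_motif, strrep("C", 35))
  expect_equal(nrow(scan_sequence(as_promoter(s))), 0L)
  m <- scan_sequence(as_promoter(s), both_strands = TRUE)
  expect_equal(nrow(m), 1L)
  expect_equal(m$strand_scanned, "antisense")
  expect_equal(m$pattern_name, "head_head")
  # the mirrored window must cover exactly the planted positions 51..65,
  # i.e. offsets -50..-36 of the 100-nt promoter
  expect_equal(m$start_offset, -50L)
  expect_equal(m$window_seq, motif)
})

test_that("custom pattern files are parsed and validated", {
  pf <- tempfile(fileext = ".tsv")
  writeLines(c("name\tconsensus15", "my_pat\tNTTCNNGAANNNNNN"), pf)
  pats <- read_patterns(pf)
  expect_equal(pats$name, "my_pat")
  m <- scan_sequence(as_promoter("ATTCGGGAAACGTAC"), pats)
  expect_equal(m$pattern_name, "my_pat")

  bad <- tempfile(fileext = ".tsv")
  writeLines("short\tNTTC", bad)
  expect_error(read_patterns(bad), class = "hseprom_bad_pattern")
  dup <- tempfile(fileext = ".tsv")
  writeLines(c("p\tNTTCNNGAANNNNNN", "p\tNGAANNTCCNNNNNN"), dup)
  expect_error(read_patterns(dup), class = "hseprom_duplicate_id")
})

test_that("BED export maps match windows back to forward-strand contig coordinates", {
  set.seed(303)
  g <- gen_promoter_set(4, c(2, 1, 1), window = 400, seed = 17)
  prom <- extract_promoters(g$genome, g$genes, window = 400)
  m <- scan_promoters(prom)
  bed <- tempfile(fileext = ".bed")
  write_matches_bed(m, prom, bed)
  tab <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(ncol(tab), 6L)
  expect_equal(nrow(tab), nrow(m))
  # every BED interval, read back from the contig and oriented by strand,
  # must reproduce the matched window sequence
  for (i in seq_len(nrow(tab))) {
    seq <- Biostrings::subseq(g$genome[[tab$V1[i]]], tab$V2[i] + 1L, tab$V3[i])
    if (tab$V6[i] == "-")
      seq <- Biostrings::reverseComplement(seq)
    expect_equal(as.character(seq), m$window_seq[i])
  }
})
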