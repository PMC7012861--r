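# shared fixture builders (all fixtures are generated in code)

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

write_fasta <- function(named_seqs, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(named_seqs), function(id)
    c(paste0(">", id), named_seqs[[id]]))), path)
  path
}

write_bed6 <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path)
  path
}

write_gff3 <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

# promoter-shaped row around a bare sequence, for scanner-level tests
as_promoter <- function(sequence, gene_id = "g1") {
  data.frame(gene_id = gene_id, sequence = sequence,
             requested_length = nchar(sequence),
             actual_length = nchar(sequence), truncated = FALSE,
             contig_id = "c1", span_start = 1L,
             span_end = nchar(sequence), strand = "+",
             stringsAsFactors = FALSE)
}

# oracle matches (no gene_id) vs scanner matches (sense only)
expect_scan_equals_oracle <- function(sequence, patterns = hse_patterns()) {
  got <- scan_sequence(as_promoter(sequence), patterns)
  ora <- brute_force_oracle(sequence, patterns)
  expect_equal(got[, c("pattern_name", "start_offset", "window_seq")],
               ora, ignore_attr = TRUE)
}
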