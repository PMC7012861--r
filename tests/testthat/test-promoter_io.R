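test_that("load_genome normalises case and rejects bad inputs distinctly", {
  fa <- write_fasta(list(c1 = "acgt"))
  g <- load_genome(fa)
  expect_length(g, 1)
  expect_equal(as.character(g[["c1"]]), "ACGT")

  dup <- write_fasta(list(c1 = "ACGT", c1 = "GGCC"))
  expect_error(load_genome(dup), class = "hseprom_duplicate_id")

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(load_genome(empty), class = "hseprom_empty_input")

  expect_error(load_genome(tempfile()), class = "hseprom_missing_file")

  bad <- write_fasta(list(c1 = "ACGZ"))
  expect_error(load_genome(bad), class = "hseprom_invalid_sequence")

  # IUPAC ambiguity letters are not load-time errors
  amb <- write_fasta(list(c1 = "ACGTNRYSWKM"))
  expect_equal(as.character(load_genome(amb)[["c1"]]), "ACGTNRYSWKM")
})

test_that("load_genes converts BED and GFF3 anchors to the forward-strand ATG", {
  bed <- write_bed6(c("c1\t2999\t5000\tg1\t0\t+",
                      "c1\t100\t500\tg2\t0\t-"))
  gm <- load_genes(bed, "bed")
  expect_equal(gm$atg_pos[gm$gene_id == "g1"], 3000L)
  expect_equal(gm$strand[gm$gene_id == "g1"], "+")
  expect_equal(gm$atg_pos[gm$gene_id == "g2"], 500L)

  gff <- write_gff3(c("c1\tsrc\tgene\t3000\t5000\t.\t+\t.\tID=g1",
                      "c1\tsrc\tgene\t101\t500\t.\t-\t.\tID=g2"))
  gm2 <- load_genes(gff, "gff3")
  expect_equal(gm2$atg_pos[gm2$gene_id == "g1"], 3000L)
  expect_equal(gm2$atg_pos[gm2$gene_id == "g2"], 500L)

  nostrand <- write_gff3("c1\tsrc\tgene\t10\t20\t.\t.\t.\tID=g3")
  expect_error(load_genes(nostrand, "gff3"), class = "hseprom_unknown_strand")
})

test_that("extract_upstream applies the documented coordinate arithmetic", {
  set.seed(11)
  contig <- rand_seq(5000)
  genome <- load_genome(write_fasta(list(c1 = contig)))

  plus <- extract_upstream(genome,
                           list(gene_id = "g1", contig_id = "c1",
                                atg_pos = 3001, strand = "+"))
  expect_equal(c(plus$span_start, plus$span_end), c(1001, 3000))
  expect_equal(plus$actual_length, 2000L)
  expect_false(plus$truncated)
  expect_equal(plus$sequence, substr(contig, 1001, 3000))

  contig3k <- substr(contig, 1, 3000)
  genome3k <- load_genome(write_fasta(list(c1 = contig3k)))
  minus <- extract_upstream(genome3k,
                            list(gene_id = "g2", contig_id = "c1",
                                 atg_pos = 500, strand = "-"))
  expect_equal(c(minus$span_start, minus$span_end), c(501, 2500))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(contig3k, 501, 2500))))
  expect_equal(minus$sequence, rc)

  expect_warning(
    trunc <- extract_upstream(genome,
                              list(gene_id = "g3", contig_id = "c1",
                                   atg_pos = 100, strand = "+")),
    "truncated")
  expect_equal(c(trunc$span_start, trunc$span_end), c(1, 99))
  expect_equal(trunc$actual_length, 99L)
  expect_true(trunc$truncated)

  expect_error(
    extract_upstream(genome, list(gene_id = "g4", contig_id = "c1",
                                  atg_pos = 1, strand = "+")),
    class = "hseprom_empty_promoter")
  expect_error(
    extract_upstream(genome, list(gene_id = "g5", contig_id = "nope",
                                  atg_pos = 10, strand = "+")),
    class = "hseprom_unknown_contig")
  expect_error(
    extract_upstream(genome, list(gene_id = "g6", contig_id = "c1",
                                  atg_pos = 9999, strand = "+")),
    class = "hseprom_coordinate_out_of_range")
})

test_that("promoter FASTA round-trips sequences, lengths and coordinates", {
  set.seed(22)
  genome <- load_genome(write_fasta(list(c1 = rand_seq(4000),
                                         c2 = rand_seq(3000))))
  genes <- data.frame(gene_id = c("gA", "gB", "gC"),
                      contig_id = c("c1", "c1", "c2"),
                      atg_pos = c(2500, 900, 1200),
                      strand = c("+", "-", "+"))
  prom <- suppressWarnings(extract_promoters(genome, genes))
  fa <- tempfile(fileext = ".fa")
  write_promoters(prom, fa)
  back <- read_promoters(fa)
  expect_equal(back$gene_id, prom$gene_id)
  expect_equal(back$sequence, prom$sequence)
  expect_equal(back$actual_length, prom$actual_length)
  expect_equal(back$span_start, prom$span_start)
  expect_equal(back$span_end, prom$span_end)
  expect_equal(back$strand, prom$strand)
})

test_that("strand symmetry: mirrored annotation on the revcomp contig gives the same promoter", {
  set.seed(33)
  for (i in 1:5) {
    L <- sample(500:1500, 1)
    fwd <- rand_seq(L)
    atg <- sample(300:L, 1)
    rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
    genome <- load_genome(write_fasta(list(f = fwd, r = rev)))
    w <- sample(50:400, 1)
    p1 <- suppressWarnings(extract_upstream(
      genome, list(gene_id = "g", contig_id = "f", atg_pos = atg,
                   strand = "+"), window = w))
    p2 <- suppressWarnings(extract_upstream(
      genome, list(gene_id = "g", contig_id = "r",
                   atg_pos = L - atg + 1, strand = "-"), window = w))
    expect_identical(p1$sequence, p2$sequence)
    expect_identical(p1$actual_length, p2$actual_length)
  }
})

test_that("truncation accounting: actual length plus edge shortfall equals the request", {
  set.seed(44)
  genome <- load_genome(write_fasta(list(c1 = rand_seq(1000))))
  for (atg in c(2, 50, 500, 999)) {
    p <- suppressWarnings(extract_upstream(
      genome, list(gene_id = "g", contig_id = "c1", atg_pos = atg,
                   strand = "+"), window = 600))
    shortfall <- max(0, 600 - (atg - 1))
    expect_equal(p$actual_length + shortfall, 600)
    expect_equal(p$truncated, p$actual_length < 600)
  }
  # minus strand: shortfall against the right contig edge
  for (atg in c(300, 950)) {
    p <- suppressWarnings(extract_upstream(
      genome, list(gene_id = "g", contig_id = "c1", atg_pos = atg,
                   strand = "-"), window = 600))
    shortfall <- max(0, 600 - (1000 - atg))
    expect_equal(p$actual_length + shortfall, 600)
  }
})
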