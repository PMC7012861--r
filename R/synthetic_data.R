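#' Generate contigs with promoters carrying planted HSEs
#'
#' Builds one contig per gene: a fixed-length upstream region followed (in
#' gene orientation) by a short gene body starting at the ATG. The
#' upstream region is composed of C/G-only spacer into which the built-in
#' HSE consensi are planted at random offsets, with every `N` position of
#' a planted motif also filled from C/G. Because the fixed core triplets
#' (TTC/GAA/TCC) are the only source of A or T, and planted motifs are
#' kept >= 30 nt apart start-to-start (so no 15-nt window can span two
#' motifs), sense-strand scanning recovers exactly the planted
#' (offset, type) set — the generator's defining trick. Genes alternate
#' between the `+` and `-` contig strand to exercise strand handling.
#'
#' @param n_genes Number of genes/contigs.
#' @param counts_per_gene Either a length-3 vector
#'   `c(tail_tail, head_head, step_gap)` applied to every gene, or an
#'   `n_genes` x 3 matrix/data frame of per-gene counts.
#' @param window Upstream region length in nt (default 2000).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return List with `genome` (named `DNAStringSet`), `genes` (gene-model
#'   data frame as from [load_genes()]), `planted` (data frame `gene_id`,
#'   `pattern_name`, `start_offset`) and `expected_counts` (an
#'   [hse_count_table()]-shaped data frame).
#' @export
gen_promoter_set <- function(n_genes, counts_per_gene = c(2, 2, 2),
                             window = 2000L, seed = 1L) {
  window <- as.integer(window)
  if (is.null(dim(counts_per_gene)))
    counts_per_gene <- matrix(rep(as.integer(counts_per_gene), each = n_genes),
                              nrow = n_genes)
  counts_per_gene <- as.matrix(counts_per_gene)
  if (nrow(counts_per_gene) != n_genes || ncol(counts_per_gene) != 3L)
    abort_hseprom("hseprom_bad_parameter",
                  "counts_per_gene must be length 3 or an n_genes x 3 table")
  spacing <- 30L  # no 15-nt window can bridge two motifs this far apart
  kmax <- max(rowSums(counts_per_gene))
  # need slack >= kmax for distinct draws (see sampling below)
  if (kmax > 0L && window - 14L - (kmax - 1L) * spacing < kmax)
    abort_hseprom("hseprom_overpacked",
                  sprintf("cannot place %d motifs %d nt apart in %d nt",
                          kmax, spacing, window))
  pats <- hse_patterns()
  body_len <- 60L
  withr::with_seed(seed, {
    genomes <- character(n_genes)
    ids <- sprintf("g%03d", seq_len(n_genes))
    contigs <- sprintf("contig_%03d", seq_len(n_genes))
    strands <- rep(c("+", "-"), length.out = n_genes)
    planted <- list()
    for (i in seq_len(n_genes)) {
      cnt <- counts_per_gene[i, ]
      k <- sum(cnt)
      up <- sample(c("C", "G"), window, replace = TRUE)
      offs <- integer(0)
      if (k > 0L) {
        # sorted distinct draws + 30i stagger give start-to-start gaps >= 31
        slack <- window - 14L - (k - 1L) * spacing
        starts <- sort(sample.int(slack, k)) + (seq_len(k) - 1L) * spacing
        types <- sample(rep(pats$name, times = cnt))
        for (j in seq_len(k)) {
          motif <- strsplit(pats$consensus[match(types[j], pats$name)],
                            "")[[1]]
          nn <- motif == "N"
          motif[nn] <- sample(c("C", "G"), sum(nn), replace = TRUE)
          up[starts[j]:(starts[j] + 14L)] <- motif
        }
        offs <- starts - window - 1L
        planted[[i]] <- data.frame(gene_id = ids[i], pattern_name = types,
                                   start_offset = offs,
                                   stringsAsFactors = FALSE)
      }
      body <- c("A", "T", "G",
                sample(c("C", "G"), body_len - 3L, replace = TRUE))
      fwd <- paste(c(up, body), collapse = "")
      if (strands[i] == "+") {
        genomes[i] <- fwd
      } else {
        genomes[i] <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
      }
    }
  })
  genome <- Biostrings::DNAStringSet(genomes)
  names(genome) <- contigs
  atg <- ifelse(strands == "+", window + 1L, body_len)
  genes <- data.frame(gene_id = ids, contig_id = contigs,
                      atg_pos = as.integer(atg), strand = strands,
                      stringsAsFactors = FALSE)
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(gene_id = character(), pattern_name = character(),
               start_offset = integer(), stringsAsFactors = FALSE)
  expected <- data.frame(gene_id = ids,
                         n_tail_tail = counts_per_gene[, 1],
                         n_head_head = counts_per_gene[, 2],
                         n_step_gap = counts_per_gene[, 3],
                         n_total = rowSums(counts_per_gene),
                         stringsAsFactors = FALSE)
  list(genome = genome, genes = genes, planted = planted,
       expected_counts = expected)
}

#' Generate a Ct table with known true fold inductions
#'
#' Emulates the standard two-condition RT-qPCR design (three biological x
#' three technical replicates, shared reference gene): control target Ct
#' is drawn around `base_ct_target`, the heat-shock target Ct is shifted
#' down by `log2(true_fold)`, and the reference gene is drawn around
#' `base_ct_ref` in both conditions. Gaussian noise of `noise_sd` cycles
#' is applied per technical replicate; optional biological variation
#' (`bio_sd`, log2 scale) shifts whole replicates.
#'
#' @param truths Data frame with columns `gene` and `true_fold`.
#' @param reference Reference gene name (default `"28s_rrna"`).
#' @param n_bio,n_tech Numbers of biological and technical replicates
#'   (defaults 3 and 3).
#' @param base_ct_target,base_ct_ref Baseline mean Ct of targets and
#'   reference (defaults 25 and 12 cycles).
#' @param noise_sd Technical Ct noise SD in cycles (default 0.2).
#' @param bio_sd Biological per-replicate shift SD in cycles (default 0).
#' @param seed Integer seed.
#' @return Ct data frame `gene`, `condition`, `bio_rep`, `tech_rep`, `ct`
#'   including the reference gene's rows.
#' @export
gen_ct_dataset <- function(truths, reference = "28s_rrna",
                           n_bio = 3L, n_tech = 3L,
                           base_ct_target = 25, base_ct_ref = 12,
                           noise_sd = 0.2, bio_sd = 0, seed = 1L) {
  if (noise_sd < 0 || bio_sd < 0)
    abort_hseprom("hseprom_bad_parameter", "noise SDs must be >= 0")
  if (any(truths$true_fold <= 0))
    abort_hseprom("hseprom_bad_parameter", "true_fold must be positive")
  conds <- c("control", "heat_shock")
  withr::with_seed(seed, {
    rows <- list()
    for (g in seq_len(nrow(truths))) {
      shift <- log2(truths$true_fold[g])
      for (cond in conds) for (b in seq_len(n_bio)) {
        mu <- base_ct_target - if (cond == "heat_shock") shift else 0
        mu <- mu + rnorm(1, 0, bio_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = truths$gene[g], condition = cond, bio_rep = b,
          tech_rep = seq_len(n_tech),
          ct = rnorm(n_tech, mu, noise_sd), stringsAsFactors = FALSE)
      }
    }
    for (cond in conds) for (b in seq_len(n_bio)) {
      mu <- base_ct_ref + rnorm(1, 0, bio_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = reference, condition = cond, bio_rep = b,
        tech_rep = seq_len(n_tech),
        ct = rnorm(n_tech, mu, noise_sd), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a reporter-assay table with known induction ratios
#'
#' Emulates a heat-shock reporter time course: control specific activity
#' is the construct's basal level under multiplicative log-normal noise;
#' heat-shock activity follows a monotone log-linear ramp from 1x at 0 hr
#' to the construct's `induction_ratio` at `peak_time`, staying at the
#' ratio afterwards. Luminescence is specific activity times the (noisy,
#' truncated-positive) protein amount, so protein normalisation is
#' exercised. The log-normal noise is mean-one on the natural scale, so
#' ratio estimates are unbiased.
#'
#' @param constructs Data frame with columns `construct`, `basal`
#'   (RLU/ug) and `induction_ratio`.
#' @param timepoints Hours post-heat-shock (default
#'   `c(0, 1, 2, 4, 6, 12, 24)`).
#' @param peak_time Timepoint (hours) at which the ramp reaches the full
#'   ratio (default 6).
#' @param n Replicates per condition and timepoint (default 5).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0.15).
#' @param protein_mean,protein_sd Protein amount distribution in ug
#'   (defaults 50 and 2; truncated at a small positive floor).
#' @param seed Integer seed.
#' @return Reporter data frame `construct`, `condition`, `timepoint`,
#'   `replicate`, `rlu`, `protein_ug`.
#' @export
gen_reporter_dataset <- function(constructs,
                                 timepoints = c(0, 1, 2, 4, 6, 12, 24),
                                 peak_time = 6, n = 5L, noise_cv = 0.15,
                                 protein_mean = 50, protein_sd = 2,
                                 seed = 1L) {
  if (noise_cv < 0)
    abort_hseprom("hseprom_bad_parameter", "noise_cv must be >= 0")
  if (any(constructs$basal <= 0) || any(constructs$induction_ratio <= 0))
    abort_hseprom("hseprom_bad_parameter",
                  "basal and induction_ratio must be positive")
  sdlog <- sqrt(log(1 + noise_cv^2))
  meanlog <- -sdlog^2 / 2  # mean-one multiplicative noise
  profile <- function(ratio, t)
    ratio^(pmin(t, peak_time) / peak_time)
  withr::with_seed(seed, {
    rows <- list()
    for (g in seq_len(nrow(constructs))) {
      for (t in timepoints) for (cond in c("control", "heat_shock")) {
        sa <- constructs$basal[g] *
          (if (cond == "heat_shock")
             profile(constructs$induction_ratio[g], t) else 1) *
          exp(rnorm(n, meanlog, sdlog))
        prot <- pmax(rnorm(n, protein_mean, protein_sd), 0.1)
        rows[[length(rows) + 1L]] <- data.frame(
          construct = constructs$construct[g], condition = cond,
          timepoint = t, replicate = seq_len(n),
          rlu = sa * prot, protein_ug = prot, stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
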