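#' Average technical replicates of a Ct table
#'
#' Collapses technical replicates to one mean Ct per
#' (gene, condition, biological replicate) cell. A dispersion flag marks
#' cells whose technical range exceeds 0.5 cycles, the usual bench QC
#' threshold. The observed gene x condition x bio_rep grid must be
#' complete.
#'
#' @param records Data frame with columns `gene`, `condition`, `bio_rep`,
#'   `tech_rep`, `ct` (cycles, positive and finite;
#'   (gene, condition, bio_rep, tech_rep) unique).
#' @return Data frame `gene`, `condition`, `bio_rep`, `mean_ct`, `n_tech`,
#'   `dispersion_flag`.
#' @export
aggregate_technical <- function(records) {
  need <- c("gene", "condition", "bio_rep", "tech_rep", "ct")
  if (!all(need %in% names(records)))
    abort_hseprom("hseprom_parse_error",
                  sprintf("Ct table needs columns: %s",
                          paste(need, collapse = ", ")))
  if (any(!is.finite(records$ct)) || any(records$ct <= 0))
    abort_hseprom("hseprom_bad_ct", "all Ct values must be positive and finite")
  key <- interaction(records$gene, records$condition, records$bio_rep,
                     records$tech_rep, drop = TRUE)
  if (anyDuplicated(key))
    abort_hseprom("hseprom_duplicate_id",
                  "duplicate (gene, condition, bio_rep, tech_rep) measurement")
  grid <- expand.grid(gene = unique(records$gene),
                      condition = unique(records$condition),
                      bio_rep = unique(records$bio_rep),
                      stringsAsFactors = FALSE)
  cell <- paste(records$gene, records$condition, records$bio_rep, sep = "\r")
  missing <- !(paste(grid$gene, grid$condition, grid$bio_rep, sep = "\r") %in%
               cell)
  if (any(missing)) {
    m <- grid[which(missing)[1], ]
    abort_hseprom("hseprom_missing_cell",
                  sprintf("no Ct records for gene=%s condition=%s bio_rep=%s",
                          m$gene, m$condition, m$bio_rep))
  }
  agg <- aggregate(ct ~ gene + condition + bio_rep, data = records,
                   FUN = function(x) c(mean = mean(x), n = length(x),
                                       rng = diff(range(x))))
  out <- data.frame(gene = agg$gene, condition = agg$condition,
                    bio_rep = agg$bio_rep,
                    mean_ct = agg$ct[, "mean"],
                    n_tech = as.integer(agg$ct[, "n"]),
                    dispersion_flag = agg$ct[, "rng"] > 0.5,
                    stringsAsFactors = FALSE)
  out[order(out$gene, out$condition, out$bio_rep), , drop = FALSE]
}

#' Delta-Ct of a target against the reference gene
#'
#' @param mean_ct_target Mean Ct of the target gene (cycles).
#' @param mean_ct_reference Mean Ct of the reference gene in the same
#'   sample.
#' @return `mean_ct_target - mean_ct_reference` (vectorised).
#' @export
delta_ct <- function(mean_ct_target, mean_ct_reference) {
  if (any(!is.finite(mean_ct_target)) || any(!is.finite(mean_ct_reference)))
    abort_hseprom("hseprom_bad_ct", "Ct means must be finite")
  mean_ct_target - mean_ct_reference
}

#' Basal expression relative to the reference gene
#'
#' Expression level expressed as fold change over the reference gene,
#' `2^-dCt`, under the Livak assumption of amplification efficiency 2.
#'
#' @param dct Delta-Ct value(s).
#' @return `2^-dct`.
#' @export
basal_expression <- function(dct) {
  if (any(!is.finite(dct)))
    abort_hseprom("hseprom_bad_ct", "dCt must be finite")
  2^(-dct)
}

#' Pooled-variance two-sample t-test
#'
#' Two-sided independent-samples Student t-test with pooled variance and
#' `df = n_x + n_y - 2` (the classic "equal variances assumed" row).
#' Degenerate inputs are handled explicitly: two zero-variance groups with
#' equal means have no defined statistic and raise an error; zero variance
#' with different means is reported as an infinite statistic with the
#' p-value at the positive underflow limit, flagged.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return List with `t_stat`, `df`, `p_value`, `flag` (`NA` or a short
#'   string describing a degenerate case).
#' @export
ttest_two_groups <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    abort_hseprom("hseprom_too_few_reps",
                  "each group needs at least 2 observations")
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y))
      abort_hseprom("hseprom_undefined_statistic",
                    "both groups constant and equal: t-statistic undefined")
    return(list(t_stat = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2L,
                p_value = .Machine$double.xmin,
                flag = "zero_variance"))
  }
  tt <- tryCatch(
    t.test(x, y, var.equal = TRUE),
    # numerically constant data below t.test's internal tolerance
    error = function(e) NULL
  )
  if (is.null(tt)) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      abort_hseprom("hseprom_undefined_statistic",
                    "both groups constant and equal: t-statistic undefined")
    return(list(t_stat = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2L,
                p_value = .Machine$double.xmin,
                flag = "zero_variance"))
  }
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, flag = NA_character_)
}

#' Fold induction by the 2^-ddCt method
#'
#' Computes per-biological-replicate ddCt between treated and control dCt
#' values and the corresponding folds `2^-ddCt`. By default replicates are
#' paired by index between conditions (ddCt computed for each biological
#' replicate); the unpaired mode references every treated replicate to the
#' mean control dCt. The significance test is applied to the dCt values
#' (approximately normal on the cycle scale), not to the log-normal folds.
#'
#' @param treated_dct Numeric vector of per-replicate dCt under treatment.
#' @param control_dct Numeric vector of per-replicate dCt under control.
#' @param paired Pair replicates by index (default `TRUE`); lengths must
#'   then agree.
#' @return List with `fold_per_bio_rep`, `fold_mean`, `fold_sd`, `t_stat`,
#'   `df`, `p_value`, `significant` (at alpha = 0.05) and `flag`.
#' @export
fold_induction_ddct <- function(treated_dct, control_dct, paired = TRUE) {
  if (length(treated_dct) < 1L || length(control_dct) < 1L)
    abort_hseprom("hseprom_too_few_reps", "need >= 1 replicate per group")
  if (paired && length(treated_dct) != length(control_dct))
    abort_hseprom("hseprom_pairing_error",
                  "paired ddCt needs equal replicate counts per condition")
  ddct <- if (paired) treated_dct - control_dct
          else treated_dct - mean(control_dct)
  folds <- 2^(-ddct)
  res <- list(fold_per_bio_rep = folds,
              fold_mean = mean(folds),
              fold_sd = if (length(folds) > 1L) sd(folds) else NA_real_,
              t_stat = NA_real_, df = NA_real_, p_value = NA_real_,
              significant = NA, flag = NA_character_)
  if (length(treated_dct) >= 2L && length(control_dct) >= 2L) {
    tt <- tryCatch(ttest_two_groups(treated_dct, control_dct),
                   hseprom_undefined_statistic = function(e)
                     list(t_stat = NA_real_, df = NA_real_,
                          p_value = NA_real_, flag = "undefined_statistic"))
    res[c("t_stat", "df", "p_value", "flag")] <-
      tt[c("t_stat", "df", "p_value", "flag")]
    if (is.finite(res$p_value) || identical(res$p_value, .Machine$double.xmin))
      res$significant <- res$p_value < 0.05
  } else {
    res$flag <- "too_few_reps_for_test"
  }
  res
}

#' Full relative-quantification analysis of a Ct table
#'
#' Runs the 2^-ddCt pipeline end to end: technical replicates are
#' averaged, each target gene's Ct is referenced to the reference gene
#' within the same (condition, biological replicate), per-replicate ddCt
#' and folds are computed between the treated and control conditions, and
#' the treated-vs-control dCt values are compared by pooled t-test.
#'
#' @param records Ct table (see [aggregate_technical()]).
#' @param reference Name of the reference gene (e.g. the 28S rRNA gene).
#' @param treated,control Condition labels (defaults `"heat_shock"`,
#'   `"control"`).
#' @param paired Pair biological replicates by index (default `TRUE`).
#' @return Data frame with one row per target gene: `gene`, `fold_mean`,
#'   `fold_sd`, `t_stat`, `df`, `p_value`, `significant`, `flag`, sorted
#'   by `gene`.
#' @export
ddct_analysis <- function(records, reference,
                          treated = "heat_shock", control = "control",
                          paired = TRUE) {
  agg <- aggregate_technical(records)
  if (!reference %in% agg$gene)
    abort_hseprom("hseprom_missing_reference",
                  sprintf("reference gene '%s' absent from Ct table",
                          reference))
  for (cond in c(treated, control))
    if (!cond %in% agg$condition)
      abort_hseprom("hseprom_missing_cell",
                    sprintf("condition '%s' absent from Ct table", cond))
  ref <- agg[agg$gene == reference, ]
  ref_key <- paste(ref$condition, ref$bio_rep, sep = "\r")
  targets <- sort(setdiff(unique(agg$gene), reference))
  rows <- lapply(targets, function(g) {
    sub <- agg[agg$gene == g, ]
    ref_ct <- ref$mean_ct[match(paste(sub$condition, sub$bio_rep, sep = "\r"),
                                ref_key)]
    dct <- delta_ct(sub$mean_ct, ref_ct)
    tr <- dct[sub$condition == treated][order(sub$bio_rep[sub$condition == treated])]
    ct <- dct[sub$condition == control][order(sub$bio_rep[sub$condition == control])]
    res <- fold_induction_ddct(tr, ct, paired = paired)
    data.frame(gene = g, fold_mean = res$fold_mean, fold_sd = res$fold_sd,
               t_stat = res$t_stat, df = res$df, p_value = res$p_value,
               significant = res$significant, flag = res$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a Ct table from delimited text
#'
#' @param path CSV or TSV with header `gene,condition,bio_rep,tech_rep,ct`.
#' @param sep Field separator (default `","`).
#' @return Validated Ct data frame.
#' @export
read_ct_table <- function(path, sep = ",") {
  if (!file.exists(path))
    abort_hseprom("hseprom_missing_file",
                  sprintf("Ct table not found: %s", path))
  tab <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene", "condition", "bio_rep", "tech_rep", "ct")
  if (!all(need %in% names(tab)))
    abort_hseprom("hseprom_parse_error",
                  sprintf("Ct table needs columns: %s",
                          paste(need, collapse = ", ")))
  tab
}

#' Write a ddCt result table as TSV
#'
#' Columns `gene  fold_mean  fold_sd  t_stat  p_value  significant`.
#'
#' @param results Result data frame from [ddct_analysis()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_induction_tsv <- function(results, path) {
  cols <- c("gene", "fold_mean", "fold_sd", "t_stat", "p_value",
            "significant")
  write.table(results[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
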