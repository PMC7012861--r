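#' Protein-normalised luciferase activity
#'
#' Specific activity of one lysate: luminescence divided by total protein
#' (RLU per microgram).
#'
#' @param rlu Luminescence reading(s), non-negative.
#' @param protein_ug Protein amount(s) in micrograms, strictly positive.
#' @return `rlu / protein_ug` (vectorised).
#' @export
specific_activity <- function(rlu, protein_ug) {
  if (any(!is.finite(rlu)) || any(rlu < 0))
    abort_hseprom("hseprom_bad_measurement",
                  "luminescence must be non-negative and finite")
  if (any(!is.finite(protein_ug)) || any(protein_ug <= 0))
    abort_hseprom("hseprom_bad_measurement",
                  "protein amount must be strictly positive")
  rlu / protein_ug
}

#' Reporter fold induction between heat-shock and control
#'
#' Fold induction is the ratio of mean specific activities,
#' `mean(hs) / mean(ctrl)`; the p-value comes from the pooled two-sample
#' t-test on the raw specific activities.
#'
#' @param hs Specific activities under heat shock (>= 1 value).
#' @param ctrl Specific activities under control (>= 1 value; positive
#'   mean).
#' @return List with `mean_hs`, `mean_ctrl`, `fold`, `t_stat`, `df`,
#'   `p_value`, `flag`.
#' @export
fold_induction <- function(hs, ctrl) {
  if (length(hs) < 1L || length(ctrl) < 1L)
    abort_hseprom("hseprom_too_few_reps", "need >= 1 value per condition")
  if (mean(ctrl) == 0)
    abort_hseprom("hseprom_zero_control",
                  "control mean activity is zero; fold undefined")
  res <- list(mean_hs = mean(hs), mean_ctrl = mean(ctrl),
              fold = mean(hs) / mean(ctrl),
              t_stat = NA_real_, df = NA_real_, p_value = NA_real_,
              flag = NA_character_)
  if (length(hs) >= 2L && length(ctrl) >= 2L) {
    tt <- tryCatch(ttest_two_groups(hs, ctrl),
                   hseprom_undefined_statistic = function(e)
                     list(t_stat = NA_real_, df = NA_real_,
                          p_value = NA_real_, flag = "undefined_statistic"))
    res[c("t_stat", "df", "p_value", "flag")] <-
      tt[c("t_stat", "df", "p_value", "flag")]
  } else {
    res$flag <- "too_few_reps_for_test"
  }
  res
}

validate_reporter <- function(records) {
  need <- c("construct", "condition", "timepoint", "replicate", "rlu")
  if (!"protein_ug" %in% names(records) && "protein" %in% names(records))
    names(records)[names(records) == "protein"] <- "protein_ug"
  if (!all(c(need, "protein_ug") %in% names(records)))
    abort_hseprom("hseprom_parse_error",
                  sprintf("reporter table needs columns: %s, protein_ug",
                          paste(need, collapse = ", ")))
  key <- interaction(records$construct, records$condition,
                     records$timepoint, records$replicate, drop = TRUE)
  if (anyDuplicated(key))
    abort_hseprom("hseprom_duplicate_id",
                  "duplicate (construct, condition, timepoint, replicate)")
  specific_activity(records$rlu, records$protein_ug)  # validates ranges
  records
}

#' Time-course fold-induction summary of a reporter experiment
#'
#' Normalises each well to specific activity, then computes the
#' heat-shock/control fold induction for every (construct, timepoint)
#' cell, pairing conditions within the same timepoint. Also reports, per
#' construct, the timepoint of maximum fold (ties resolved to the earliest
#' timepoint).
#'
#' @param records Reporter table with columns `construct`, `condition`
#'   (`"heat_shock"` / `"control"`), `timepoint` (hours post-heat-shock),
#'   `replicate`, `rlu`, `protein_ug`.
#' @param treated,control Condition labels.
#' @return List with `induction` (data frame `construct`, `timepoint`,
#'   `mean_hs`, `mean_ctrl`, `fold`, `t_stat`, `p_value`, `significant`)
#'   and `peak` (data frame `construct`, `peak_timepoint`, `peak_fold`).
#' @export
timecourse_summary <- function(records, treated = "heat_shock",
                               control = "control") {
  records <- validate_reporter(records)
  records$sa <- specific_activity(records$rlu, records$protein_ug)
  cells <- unique(records[, c("construct", "timepoint")])
  cells <- cells[order(cells$construct, cells$timepoint), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cc <- cells[i, ]
    sub <- records[records$construct == cc$construct &
                   records$timepoint == cc$timepoint, ]
    hs <- sub$sa[sub$condition == treated]
    ct <- sub$sa[sub$condition == control]
    if (length(hs) == 0L || length(ct) == 0L)
      abort_hseprom("hseprom_missing_cell",
                    sprintf("construct=%s timepoint=%s lacks condition '%s'",
                            cc$construct, cc$timepoint,
                            if (length(hs) == 0L) treated else control))
    fi <- fold_induction(hs, ct)
    data.frame(construct = cc$construct, timepoint = cc$timepoint,
               mean_hs = fi$mean_hs, mean_ctrl = fi$mean_ctrl,
               fold = fi$fold, t_stat = fi$t_stat, p_value = fi$p_value,
               significant = !is.na(fi$p_value) & fi$p_value < 0.05,
               stringsAsFactors = FALSE)
  })
  ind <- do.call(rbind, rows)
  rownames(ind) <- NULL
  peak <- do.call(rbind, lapply(split(ind, ind$construct), function(d) {
    d <- d[order(d$timepoint), ]
    j <- which.max(d$fold)  # first maximum = earliest timepoint on ties
    data.frame(construct = d$construct[1], peak_timepoint = d$timepoint[j],
               peak_fold = d$fold[j], stringsAsFactors = FALSE)
  }))
  rownames(peak) <- NULL
  list(induction = ind, peak = peak)
}

# All maximal cliques of a small undirected graph given as a logical
# adjacency matrix (subset enumeration; fine for the <= 15 groups of a
# promoter comparison).
maximal_cliques <- function(adj) {
  k <- nrow(adj)
  subsets <- lapply(seq_len(2^k - 1), function(m) which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0))
  is_clique <- vapply(subsets, function(s)
    all(adj[s, s, drop = FALSE]), TRUE)
  cl <- subsets[is_clique]
  keep <- vapply(seq_along(cl), function(i)
    !any(vapply(seq_along(cl), function(j)
      i != j && all(cl[[i]] %in% cl[[j]]), TRUE)), TRUE)
  cl[keep]
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Fixed-effects one-way ANOVA on the raw values, followed by Tukey's
#' honestly-significant-difference test on all group pairs (studentized
#' range distribution), and a compact letter display: groups are ordered
#' by decreasing mean and letters assigned from the top so that two groups
#' share a letter exactly when their Tukey-adjusted p-value is >= `alpha`.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with
#'   >= 2 observations), e.g. constructs' specific activities.
#' @param alpha Significance level (default 0.05).
#' @param log_scale Analyse `log10(values)` instead of raw values
#'   (variance-stabilised alternative; default `FALSE`).
#' @return List with `F_stat`, `df` (numerator, denominator), `p_value`,
#'   `pairwise` (data frame `group1`, `group2`, `diff`, `p_adj`,
#'   `significant`) and `letters` (data frame `group`, `mean`, `letters`,
#'   ordered by decreasing mean).
#' @export
anova_tukey <- function(groups, alpha = 0.05, log_scale = FALSE) {
  if (!is.list(groups) || length(groups) < 2L || is.null(names(groups)) ||
      any(names(groups) == ""))
    abort_hseprom("hseprom_bad_parameter",
                  "groups must be a named list of >= 2 numeric vectors")
  if (any(lengths(groups) < 2L))
    abort_hseprom("hseprom_too_few_reps",
                  "every group needs at least 2 observations")
  if (length(groups) > 15L)
    abort_hseprom("hseprom_bad_parameter",
                  "letter display supports at most 15 groups")
  vals <- unlist(groups, use.names = FALSE)
  if (log_scale) {
    if (any(vals <= 0))
      abort_hseprom("hseprom_bad_measurement",
                    "log-scale analysis needs strictly positive values")
    vals <- log10(vals)
  }
  lab <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (all(tapply(vals, lab, var) == 0))
    abort_hseprom("hseprom_zero_variance",
                  "zero within-group variance: ANOVA undefined")
  fit <- aov(vals ~ lab)
  s <- summary(fit)[[1]]
  F_stat <- s[["F value"]][1]
  p_value <- s[["Pr(>F)"]][1]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$lab
  pair_names <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairwise <- data.frame(
    group1 = vapply(pair_names, `[`, "", 1L),
    group2 = vapply(pair_names, `[`, "", 2L),
    diff = unname(tk[, "diff"]),
    p_adj = unname(tk[, "p adj"]),
    stringsAsFactors = FALSE
  )
  pairwise$significant <- pairwise$p_adj < alpha
  means <- vapply(groups, function(g) mean(if (log_scale) log10(g) else g), 0)
  ord <- order(-means)
  gnames <- names(groups)[ord]
  k <- length(gnames)
  adj <- matrix(TRUE, k, k, dimnames = list(gnames, gnames))
  for (i in seq_len(nrow(pairwise))) {
    if (pairwise$significant[i]) {
      a <- pairwise$group1[i]; b <- pairwise$group2[i]
      adj[a, b] <- adj[b, a] <- FALSE
    }
  }
  cliques <- maximal_cliques(adj)
  # order letter classes by their best (highest-mean) member
  cliques <- cliques[order(vapply(cliques, min, 0L))]
  lett <- rep("", k)
  for (ci in seq_along(cliques))
    lett[cliques[[ci]]] <- paste0(lett[cliques[[ci]]], letters[ci])
  list(F_stat = F_stat,
       df = c(s[["Df"]][1], s[["Df"]][2]),
       p_value = p_value,
       pairwise = pairwise,
       letters = data.frame(group = gnames, mean = means[ord],
                            letters = lett, stringsAsFactors = FALSE))
}

#' Read a reporter-assay table from CSV
#'
#' @param path CSV with header
#'   `construct,condition,timepoint,replicate,rlu,protein_ug`.
#' @return Validated reporter data frame.
#' @export
read_reporter_table <- function(path) {
  if (!file.exists(path))
    abort_hseprom("hseprom_missing_file",
                  sprintf("reporter table not found: %s", path))
  validate_reporter(read.table(path, sep = ",", header = TRUE,
                               stringsAsFactors = FALSE))
}

#' Write a reporter analysis (induction, Tukey pairs, letters) as TSVs
#'
#' @param summary Result of [timecourse_summary()].
#' @param path Output TSV path for the induction table.
#' @return `path`, invisibly.
#' @export
write_timecourse_tsv <- function(summary, path) {
  write.table(summary$induction, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
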