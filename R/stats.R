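#' Paired haptic vs non-haptic accuracy test
#'
#' Two-sided paired-sample t-test on per-subject accuracy differences
#' (haptic minus non-haptic).
#'
#' @param acc_non,acc_hap Equal-length per-subject accuracy vectors
#'   (percent), paired by subject.
#' @param alpha Significance level recorded alongside the result.
#' @return List of class `paired_stat` with `t`, `df`, `p`, `mean_diff`,
#'   `alpha`, `significant` and `degenerate` (TRUE when the differences have
#'   zero variance, in which case the statistic is undefined and `t`/`p` are
#'   `NA`).
#' @export
paired_accuracy_ttest <- function(acc_non, acc_hap, alpha = 0.05) {
  stopifnot(length(acc_non) == length(acc_hap), length(acc_non) >= 2)
  d <- acc_hap - acc_non
  if (stats::sd(d) == 0) {
    return(structure(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                          mean_diff = mean(d), alpha = alpha,
                          significant = NA, degenerate = TRUE),
                     class = "paired_stat"))
  }
  tt <- stats::t.test(acc_hap, acc_non, paired = TRUE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_diff = mean(d), alpha = alpha,
                 significant = tt$p.value < alpha, degenerate = FALSE),
            class = "paired_stat")
}

#' @export
print.paired_stat <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.3f, p = %.4g, mean diff = %.2f%s\n",
              x$df, x$t, x$p, x$mean_diff,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Mean relative accuracy growth rate
#'
#' Per subject, the relative growth `(haptic - non-haptic) / non-haptic x
#' 100`; the entry is the across-subject mean. Undefined (NA, flagged) when
#' any non-haptic accuracy is zero.
#'
#' @inheritParams paired_accuracy_ttest
#' @return List with `growth` (percent, across-subject mean), `per_subject`,
#'   and `defined`.
#' @export
growth_rate <- function(acc_non, acc_hap) {
  stopifnot(length(acc_non) == length(acc_hap), length(acc_non) >= 1)
  if (any(acc_non <= 0, na.rm = TRUE) || anyNA(acc_non) || anyNA(acc_hap))
    return(list(growth = NA_real_, per_subject = rep(NA_real_, length(acc_non)),
                defined = FALSE))
  per <- (acc_hap - acc_non) / acc_non * 100
  list(growth = mean(per), per_subject = per, defined = TRUE)
}

#' Haptic vs non-haptic statistics over an accuracy table
#'
#' For every (feature, band, pattern) cell: the paired t-test and the mean
#' growth rate across subjects, comparing the haptic against the non-haptic
#' condition. No multiple-testing correction is applied by default; an
#' optional Holm adjustment over all cells can be requested.
#'
#' @param acc An `accuracy_table` as from [evaluate_experiment()].
#' @param alpha Significance level (default 0.05).
#' @param adjust P-value adjustment method (`"none"` or any
#'   [stats::p.adjust()] method such as `"holm"`).
#' @return data.frame with one row per cell: `feature`, `band`, `pattern`,
#'   `t`, `df`, `p`, `significant`, `growth_pct`, `n_subjects`.
#' @export
accuracy_stats <- function(acc, alpha = 0.05, adjust = "none") {
  stopifnot(all(c("subject", "pattern", "condition", "feature", "band",
                  "accuracy") %in% names(acc)))
  cells <- unique(acc[, c("feature", "band", "pattern")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    sub <- acc[acc$feature == cell$feature & acc$band == cell$band &
                 acc$pattern == cell$pattern, ]
    non <- sub[sub$condition == "non-haptic", ]
    hap <- sub[sub$condition == "haptic", ]
    subj <- intersect(non$subject, hap$subject)
    a_non <- non$accuracy[match(subj, non$subject)]
    a_hap <- hap$accuracy[match(subj, hap$subject)]
    ok <- !(is.na(a_non) | is.na(a_hap))
    a_non <- a_non[ok]; a_hap <- a_hap[ok]
    if (length(a_non) >= 2 && stats::sd(a_hap - a_non) > 0) {
      st <- paired_accuracy_ttest(a_non, a_hap, alpha)
      gr <- growth_rate(a_non, a_hap)
      rows[[i]] <- data.frame(feature = cell$feature, band = cell$band,
                              pattern = cell$pattern, t = st$t, df = st$df,
                              p = st$p, growth_pct = gr$growth,
                              n_subjects = length(a_non))
    } else {
      rows[[i]] <- data.frame(feature = cell$feature, band = cell$band,
                              pattern = cell$pattern, t = NA_real_,
                              df = length(a_non) - 1L, p = NA_real_,
                              growth_pct = NA_real_,
                              n_subjects = length(a_non))
    }
  }
  out <- do.call(rbind, rows)
  if (adjust != "none") out$p <- stats::p.adjust(out$p, method = adjust)
  out$significant <- !is.na(out$p) & out$p < alpha
  out
}

#' Per-band paired test pooled over haptic patterns
#'
#' For one feature and band, averages each subject's accuracy over the
#' patterns within each condition and runs the paired haptic vs non-haptic
#' test across subjects — the band-level counterpart of the per-pattern
#' cells in [accuracy_stats()].
#'
#' @param acc An `accuracy_table`.
#' @param band Band row to test.
#' @param feature Feature kind (default `"DE"`).
#' @param alpha Significance level.
#' @return List with the `paired_stat` (`test`) and the pooled mean
#'   `growth_pct` across subjects.
#' @export
band_paired_test <- function(acc, band, feature = "DE", alpha = 0.05) {
  sub <- acc[acc$band == band & acc$feature == feature & !is.na(acc$accuracy), ]
  pooled <- stats::aggregate(accuracy ~ subject + condition, sub, mean)
  non <- pooled[pooled$condition == "non-haptic", ]
  hap <- pooled[pooled$condition == "haptic", ]
  subj <- intersect(non$subject, hap$subject)
  a_non <- non$accuracy[match(subj, non$subject)]
  a_hap <- hap$accuracy[match(subj, hap$subject)]
  list(test = paired_accuracy_ttest(a_non, a_hap, alpha),
       growth_pct = growth_rate(a_non, a_hap)$growth,
       n_subjects = length(subj))
}

feature_order <- function() c("PSD", "DE", "DASM", "DCAU")

band_row_order <- function() c(eeg_bands()$name, "total")

#' Write the report tables of a run
#'
#' Emits the four standard CSV tables: mean accuracy per feature x band for
#' each haptic pattern (non-haptic and haptic columns side by side), the
#' paired t-test p-values, and the mean growth rates — columns ordered PSD,
#' DE, DASM, DCAU; band rows delta..gamma then total. Missing cells are
#' rendered as NA. A plain-text summary marks significance at `alpha`.
#'
#' @param acc An `accuracy_table`.
#' @param stats Output of [accuracy_stats()]; recomputed if `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param alpha Significance level for the summary markers.
#' @return Invisibly, the named list of written file paths.
#' @export
render_tables <- function(acc, stats = NULL, out_dir, alpha = 0.05) {
  if (is.null(stats)) stats <- accuracy_stats(acc, alpha = alpha)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  means <- stats::aggregate(accuracy ~ pattern + condition + feature + band,
                            data = acc, FUN = mean, na.rm = TRUE,
                            na.action = stats::na.pass)
  wide_acc <- function(pat) {
    out <- data.frame(band = band_row_order())
    for (f in feature_order())
      for (cond in c("non-haptic", "haptic")) {
        v <- means$accuracy[means$pattern == pat & means$feature == f &
                              means$condition == cond]
        names(v) <- means$band[means$pattern == pat & means$feature == f &
                                 means$condition == cond]
        out[[paste0(f, ".", cond)]] <- round(v[out$band], 2)
      }
    out
  }
  wide_stat <- function(col) {
    out <- data.frame(band = band_row_order())
    for (f in feature_order())
      for (pat in sort(unique(stats$pattern))) {
        v <- stats[[col]][stats$feature == f & stats$pattern == pat]
        names(v) <- stats$band[stats$feature == f & stats$pattern == pat]
        out[[paste0(f, ".", pat)]] <- round(v[out$band], 4)
      }
    out
  }
  paths <- c(
    accuracy_haptic1 = file.path(out_dir, "accuracy_haptic1.csv"),
    accuracy_haptic2 = file.path(out_dir, "accuracy_haptic2.csv"),
    paired_tests = file.path(out_dir, "paired_tests.csv"),
    growth_rates = file.path(out_dir, "growth_rates.csv"))
  utils::write.csv(wide_acc("haptic1"), paths["accuracy_haptic1"], row.names = FALSE)
  utils::write.csv(wide_acc("haptic2"), paths["accuracy_haptic2"], row.names = FALSE)
  utils::write.csv(wide_stat("p"), paths["paired_tests"], row.names = FALSE)
  utils::write.csv(wide_stat("growth_pct"), paths["growth_rates"], row.names = FALSE)
  summ <- file.path(out_dir, "summary.txt")
  con <- file(summ, "w"); on.exit(close(con))
  writeLines(sprintf("haptic vs non-haptic paired tests (alpha = %g)", alpha), con)
  for (i in seq_len(nrow(stats)))
    writeLines(sprintf("  %-4s %-6s %-8s p = %s%s  growth = %s%%",
                       stats$feature[i], stats$band[i], stats$pattern[i],
                       format(stats$p[i], digits = 3),
                       ifelse(isTRUE(stats$significant[i]), " *", "  "),
                       format(stats$growth_pct[i], digits = 3)), con)
  invisible(c(paths, summary = summ))
}
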