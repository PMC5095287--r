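#' Group-level statistical report of a cohort
#'
#' Assembles the full battery of group comparisons relating training-induced
#' plasticity to pain: per-condition pre/post pain tests (paired t for VAS,
#' Wilcoxon signed-rank for the questionnaire total, both uncorrected, as in
#' the original analyses), one-way ANOVAs of the pain and accuracy changes
#' across the three decoder conditions, pairwise Mann-Whitney tests of the
#' questionnaire changes, Bonferroni-corrected pairwise t tests of the
#' accuracy changes, and the pooled (patient x condition, n = 30 at the
#' default design) correlations between accuracy/current changes and pain
#' changes.
#'
#' @param outcomes a [compute_outcomes()] object.
#' @return object of class `bmi_report`: named lists of `bmi_stat` results
#'   plus the per-condition summary table.
#' @export
build_report <- function(outcomes) {
  stopifnot(inherits(outcomes, "cohort_outcomes"))
  tab <- outcomes$table
  conds <- c("phantom", "random", "real")
  pain <- list(); acc <- list(); cors <- list()

  by_cond <- split(tab, factor(tab$condition, levels = conds))
  summary_tab <- do.call(rbind, lapply(conds, function(cc) {
    x <- by_cond[[cc]]
    data.frame(condition = cc, n = nrow(x),
               mean_delta_vas = mean(x$delta_vas),
               mean_delta_mpq2_total = mean(x$delta_mpq2_total),
               mean_delta_acc_contra = if ("delta_acc_contra" %in% names(x))
                 mean(x$delta_acc_contra) else NA_real_)
  }))

  for (cc in conds) {
    x <- by_cond[[cc]]
    pain[[paste0("vas_", cc)]] <-
      paired_t(rep(0, nrow(x)), x$delta_vas)
    pain[[paste0("mpq2_total_", cc)]] <- tryCatch(
      wilcoxon_signed_rank(rep(0, nrow(x)), x$delta_mpq2_total),
      error = function(e) NULL)
  }
  pain$vas_anova <- one_way_anova(tab$delta_vas, tab$condition)
  pain$mpq2_total_anova <- one_way_anova(tab$delta_mpq2_total, tab$condition)
  for (s in c("continuous", "intermittent", "neuropathic", "affective"))
    pain[[paste0("mpq2_", s, "_anova")]] <-
      one_way_anova(tab[[paste0("delta_mpq2_", s)]], tab$condition)
  prs <- list(c("real", "random"), c("real", "phantom"), c("phantom", "random"))
  for (pr in prs)
    pain[[paste0("mpq2_total_", pr[1], "_vs_", pr[2])]] <-
      mann_whitney_u(by_cond[[pr[1]]]$delta_mpq2_total,
                     by_cond[[pr[2]]]$delta_mpq2_total)

  if ("delta_acc_contra" %in% names(tab)) {
    acc$contra_anova <- one_way_anova(tab$delta_acc_contra, tab$condition)
    if ("delta_acc_ipsi" %in% names(tab))
      acc$ipsi_anova <- one_way_anova(tab$delta_acc_ipsi, tab$condition)
    for (pr in prs) {
      tt <- t.test(by_cond[[pr[1]]]$delta_acc_contra,
                   by_cond[[pr[2]]]$delta_acc_contra, var.equal = TRUE)
      acc[[paste0("contra_", pr[1], "_vs_", pr[2])]] <- bonferroni(
        new_stat(tt$statistic, "t", tt$p.value, df = unname(tt$parameter),
                 n = nrow(by_cond[[pr[1]]]) + nrow(by_cond[[pr[2]]]),
                 method = "two-sample Student's t-test"), length(prs))
    }
    cors$acc_contra_vas <- correlate(tab$delta_acc_contra, tab$delta_vas)
    cors$acc_contra_mpq2 <- correlate(tab$delta_acc_contra,
                                      tab$delta_mpq2_total, "spearman")
    if ("delta_acc_ipsi" %in% names(tab)) {
      cors$acc_ipsi_vas <- correlate(tab$delta_acc_ipsi, tab$delta_vas)
      cors$acc_ipsi_mpq2 <- correlate(tab$delta_acc_ipsi,
                                      tab$delta_mpq2_total, "spearman")
    }
  }
  if ("delta_current" %in% names(tab))
    cors$current_vas <- correlate(tab$delta_current, tab$delta_vas)
  rmap <- if (!is.null(outcomes$delta_f))
    vertexwise_correlation_map(outcomes$delta_f, tab$delta_vas) else NULL

  structure(list(summary = summary_tab, pain = pain, accuracy = acc,
                 correlations = cors, delta_f_vas_map = rmap,
                 n_pairs = nrow(tab)),
            class = "bmi_report")
}

#' @export
print.bmi_report <- function(x, ...) {
  cat(sprintf("<bmi_report> %d patient x condition pairs\n", x$n_pairs))
  print(x$summary, row.names = FALSE)
  cat("\nPain changes across conditions:\n  ")
  print(x$pain$vas_anova)
  if (!is.null(x$accuracy$contra_anova)) {
    cat("Accuracy changes (contra) across conditions:\n  ")
    print(x$accuracy$contra_anova)
  }
  if (!is.null(x$correlations$acc_contra_vas)) {
    cat("delta accuracy (contra) vs delta VAS:\n  ")
    print(x$correlations$acc_contra_vas)
  }
  invisible(x)
}
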