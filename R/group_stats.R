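new_stat <- function(statistic, name, p, df = NULL, n = NULL, method = "",
                     correction = "none", estimate = NULL) {
  structure(list(statistic = unname(statistic), statistic_name = name,
                 p_value = unname(p), df = df, n = n, method = method,
                 correction = correction, estimate = estimate),
            class = "bmi_stat")
}

#' @export
print.bmi_stat <- function(x, ...) {
  df_txt <- if (!is.null(x$df))
    sprintf("(%s)", paste(round(x$df, 1), collapse = ", ")) else ""
  cat(sprintf("%s: %s%s = %.4g, p = %.4g (%s, n = %s)\n", x$method,
              x$statistic_name, df_txt, x$statistic, x$p_value,
              x$correction, x$n %||% "?"))
  invisible(x)
}

#' Two-tailed paired Student's t test
#'
#' @param x_pre,x_post paired measurements (equal length).
#' @return a `bmi_stat` with the t statistic for post minus pre.
#' @export
paired_t <- function(x_pre, x_post) {
  if (length(x_pre) != length(x_post))
    stop("paired inputs must have equal length", call. = FALSE)
  if (length(x_pre) < 2L) stop("need n >= 2 pairs", call. = FALSE)
  if (sd(x_post - x_pre) == 0 && mean(x_post - x_pre) == 0)
    return(new_stat(0, "t", 1, df = length(x_pre) - 1, n = length(x_pre),
                    method = "paired Student's t-test", estimate = 0))
  tt <- t.test(x_post, x_pre, paired = TRUE)
  new_stat(tt$statistic, "t", tt$p.value, df = unname(tt$parameter),
           n = length(x_pre), method = "paired Student's t-test",
           estimate = unname(tt$estimate))
}

#' Two-tailed Wilcoxon signed-rank test (paired)
#'
#' Exact small-sample null when n <= 25 and the differences are untied and
#' nonzero; errors on all-zero differences rather than returning a vacuous
#' result.
#'
#' @param x_pre,x_post paired measurements.
#' @return a `bmi_stat` with the signed-rank statistic V (post minus pre).
#' @export
wilcoxon_signed_rank <- function(x_pre, x_post) {
  if (length(x_pre) != length(x_post))
    stop("paired inputs must have equal length", call. = FALSE)
  dif <- x_post - x_pre
  if (all(dif == 0))
    stop("degenerate input: all paired differences are zero", call. = FALSE)
  n_eff <- sum(dif != 0)
  exact <- n_eff <= 25 && !any(duplicated(abs(dif[dif != 0])))
  wt <- suppressWarnings(wilcox.test(x_post, x_pre, paired = TRUE,
                                     exact = exact))
  new_stat(wt$statistic, "V", wt$p.value, n = length(x_pre),
           method = "Wilcoxon signed-rank test")
}

#' Two-tailed Mann-Whitney U test
#'
#' @param a,b independent samples; the statistic is U of the first sample.
#' @return a `bmi_stat`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("need >= 2 observations per group", call. = FALSE)
  exact <- length(a) + length(b) <= 50 && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact))
  new_stat(wt$statistic, "U", wt$p.value, n = length(a) + length(b),
           method = "Mann-Whitney U-test")
}

#' Classic one-way analysis of variance
#'
#' Equal-variance one-way ANOVA, `F = MS_between / MS_within`, as used for
#' the condition contrasts.
#'
#' @param values numeric vector, or a list of group vectors (then `groups` is
#'   ignored).
#' @param groups grouping factor for `values`.
#' @return a `bmi_stat` with F and its two degrees of freedom.
#' @export
one_way_anova <- function(values, groups = NULL) {
  if (is.list(values)) {
    groups <- factor(rep(seq_along(values), lengths(values)))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) stop("need >= 2 observations per group",
                                    call. = FALSE)
  ow <- oneway.test(values ~ groups, var.equal = TRUE)
  new_stat(ow$statistic, "F", ow$p.value, df = unname(ow$parameter),
           n = length(values), method = "one-way ANOVA")
}

#' Correlation between a plasticity change and a pain change
#'
#' Pearson's r (p from the classical t approximation) or Spearman's rho
#' (exact rank null where available). Zero variance in either input is an
#' error, not a silent `NA`.
#'
#' @param delta_metric,delta_pain numeric vectors, n >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return a `bmi_stat`; the coefficient is in `estimate` and `statistic`.
#' @export
correlate <- function(delta_metric, delta_pain,
                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(delta_metric) != length(delta_pain))
    stop("inputs must have equal length", call. = FALSE)
  if (length(delta_metric) < 3L) stop("need n >= 3", call. = FALSE)
  if (!all(is.finite(delta_metric)) || !all(is.finite(delta_pain)))
    stop("inputs must be finite", call. = FALSE)
  if (sd(delta_metric) == 0 || sd(delta_pain) == 0)
    stop("undefined correlation: an input has zero variance", call. = FALSE)
  ct <- suppressWarnings(cor.test(delta_metric, delta_pain, method = method))
  new_stat(unname(ct$estimate), if (method == "pearson") "R" else "rho",
           ct$p.value, df = if (method == "pearson") unname(ct$parameter),
           n = length(delta_metric),
           method = paste0(method, " correlation"),
           estimate = unname(ct$estimate))
}

#' Bonferroni correction of a test result
#'
#' @param stat a `bmi_stat`.
#' @param m number of comparisons.
#' @return the `bmi_stat` with `p_value = min(1, m * p)` and the correction
#'   recorded.
#' @export
bonferroni <- function(stat, m) {
  stopifnot(inherits(stat, "bmi_stat"))
  m <- assert_count(m, "m")
  stat$p_value <- min(1, m * stat$p_value)
  stat$correction <- sprintf("bonferroni (m = %d)", m)
  stat
}

#' Per-vertex correlation map between F-value changes and pain changes
#'
#' Pearson r at every vertex between the across-pair vector of F changes and
#' the VAS changes (patient x condition pairs pooled, n = 30 by default).
#' A constant pain vector makes the whole map undefined; this is flagged
#' explicitly (`defined = FALSE`, NA values), never silently zeroed.
#'
#' @param delta_f_maps vertices x pairs matrix of F changes.
#' @param delta_vas length-pairs vector of VAS changes.
#' @return list of class `r_map`: `r` per vertex, `n`, `defined`.
#' @export
vertexwise_correlation_map <- function(delta_f_maps, delta_vas) {
  delta_f_maps <- as.matrix(delta_f_maps)
  if (ncol(delta_f_maps) != length(delta_vas))
    stop("number of maps and pain changes differ", call. = FALSE)
  if (sd(delta_vas) == 0)
    return(structure(list(r = rep(NA_real_, nrow(delta_f_maps)),
                          n = length(delta_vas), defined = FALSE),
                     class = "r_map"))
  xc <- delta_f_maps - rowMeans(delta_f_maps)
  yc <- delta_vas - mean(delta_vas)
  r <- as.vector(xc %*% yc) /
    (sqrt(rowSums(xc^2)) * sqrt(sum(yc^2)))
  r[rowSums(xc^2) == 0] <- NA_real_
  structure(list(r = r, n = length(delta_vas), defined = TRUE),
            class = "r_map")
}

#' @export
print.r_map <- function(x, ...) {
  if (!x$defined) cat("<r_map> undefined (constant pain change)\n")
  else cat(sprintf("<r_map> %d vertices, n = %d, r range [%.2f, %.2f]\n",
                   length(x$r), x$n, min(x$r, na.rm = TRUE),
                   max(x$r, na.rm = TRUE)))
  invisible(x)
}
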