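# Group-level statistical comparisons and method-agreement analyses on
# per-region summary tables: one-way ANOVA with Tukey HSD, paired t-test,
# Bland-Altman agreement, and Pearson correlation with both flavours of R^2.

#' Validate a group table
#'
#' Checks the long-format table used by the report functions: one value per
#' (subject, region, metric), with subject, cohort, region, metric, value
#' columns.
#'
#' @param df data.frame with columns subject, cohort, region, metric, value.
#' @return The validated data.frame (invisibly usable downstream).
#' @export
groupTable <- function(df) {
  need <- c("subject", "cohort", "region", "metric", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("group table missing columns: ",
                         paste(miss, collapse = ", "))
  key <- paste(df$subject, df$region, df$metric)
  if (anyDuplicated(key))
    stop("group table must have one value per (subject, region, metric)")
  df
}

#' One-way ANOVA with Tukey HSD post-hoc test
#'
#' Classical between/within sum-of-squares decomposition (via \code{aov})
#' with the studentized-range Tukey honest-significant-difference post-hoc
#' comparisons. Intermediate sums of squares are reported.
#'
#' @param values Numeric observations.
#' @param groups Factor (or coercible) of group membership.
#' @return List: F, p, df (between, within), ss_between, ss_within,
#'   group_means, and \code{tukey}, a data.frame of pairwise differences
#'   with adjusted p-values.
#' @export
oneWayAnovaTukey <- function(values, groups) {
  groups <- factor(groups)
  counts <- table(groups)
  if (length(counts) < 2L) stop("need at least 2 groups")
  small <- names(counts)[counts < 2]
  if (length(small))
    stop("group with fewer than 2 observations: ",
         paste(small, collapse = ", "))
  fit <- stats::aov(values ~ groups)
  tab <- stats::anova(fit)
  tk <- stats::TukeyHSD(fit)$groups
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       df = unname(tab$Df), ss_between = tab$`Sum Sq`[1],
       ss_within = tab$`Sum Sq`[2],
       group_means = tapply(values, groups, mean),
       tukey = data.frame(comparison = rownames(tk),
                          diff = tk[, "diff"], lwr = tk[, "lwr"],
                          upr = tk[, "upr"], p_adj = tk[, "p adj"],
                          row.names = NULL))
}

#' Paired t-test between two regions
#'
#' Classical two-sided paired t-test on the per-subject differences. A
#' zero-variance difference vector is degenerate: the result is flagged and
#' t reported as \code{Inf} (or 0 when the differences are all zero).
#'
#' @param a,b Paired numeric vectors (same subjects, same order).
#' @return List: t, p, df, mean_diff, degenerate (logical).
#' @export
pairedT <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- b - a
  if (stats::sd(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                p = if (mean(d) == 0) 1 else 0,
                df = length(d) - 1L, mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(b, a, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate),
       degenerate = FALSE)
}

#' Bland-Altman agreement analysis
#'
#' Bias = mean(y - x) (conventionally DTI minus histology when comparing
#' imaging against the histological reference), with limits of agreement
#' bias +/- 1.96 * SD(y - x).
#'
#' @param x Reference measurements (e.g. histology angles, degrees).
#' @param y Comparison measurements (e.g. DTI angles, degrees).
#' @return List: bias, loa_lower, loa_upper, sd_diff, n.
#' @export
blandAltman <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- y - x
  s <- stats::sd(d)
  bias <- mean(d)
  list(bias = bias, loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
       sd_diff = s, n = length(d))
}

#' Pearson correlation and coefficients of determination
#'
#' Pearson r of the pairs, plus two R^2 flavours: \code{r2_fit}, the squared
#' correlation (the R^2 of the fitted least-squares line), and
#' \code{r2_identity}, the variance explained by the identity line y = x
#' (1 - SS(y - x) / SS(y - mean(y))), the natural quantity for
#' method-agreement studies. The two differ whenever the methods disagree in
#' bias or scale, which is why a reported R^2 need not equal the square of
#' the reported r.
#'
#' @param x,y Numeric vectors, n >= 3.
#' @return List: r, r2_fit, r2_identity, n.
#' @export
correlationR2 <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  r <- stats::cor(x, y)
  list(r = r, r2_fit = r^2,
       r2_identity = 1 - sum((y - x)^2) / sum((y - mean(y))^2),
       n = length(x))
}

#' Run a metric's group comparison from a group table
#'
#' Filters a validated group table to one metric/region and runs the one-way
#' ANOVA with Tukey HSD across cohorts; subjects from all timepoints are
#' pooled unless the table was pre-filtered.
#'
#' @param table A \code{groupTable()} data.frame.
#' @param metric Metric name to test.
#' @param region Region to test within.
#' @param cohorts Cohorts to compare (default: all present).
#' @return As \code{\link{oneWayAnovaTukey}}.
#' @export
compareCohorts <- function(table, metric, region, cohorts = NULL) {
  df <- table[table$metric == metric & table$region == region, ]
  if (!is.null(cohorts)) df <- df[df$cohort %in% cohorts, ]
  if (!nrow(df)) stop("no rows for metric '", metric, "' in region '",
                      region, "'")
  oneWayAnovaTukey(df$value, df$cohort)
}
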