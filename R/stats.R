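#' Dendritic spine density
#'
#' Density = spine count / dendrite length, computed per dendrite after the
#' inclusion rules: branches shorter than 40 um are excluded, and at most 5
#' dendrites per compartment (apical/basal) per neuron are admitted, taken
#' in the order supplied.
#'
#' @param counts data frame with columns `neuron_id`, `compartment`
#'   (`"apical"` or `"basal"`), `length_um` (> 0), `spine_count` (>= 0).
#' @param min_length_um minimum admissible branch length, um.
#' @param max_per_compartment dendrite cap per compartment per neuron.
#' @param per_10um report density per 10 um instead of per um.
#' @return the admitted rows with an added `density` column.
#' @export
spine_density <- function(counts, min_length_um = 40,
                          max_per_compartment = 5, per_10um = FALSE) {
  counts <- as.data.frame(counts)
  need <- c("neuron_id", "compartment", "length_um", "spine_count")
  stopifnot(all(need %in% names(counts)))
  if (any(counts$length_um <= 0))
    stop("structural error: non-positive dendrite length", call. = FALSE)
  if (any(counts$spine_count < 0))
    stop("structural error: negative spine count", call. = FALSE)

  # cap of 5 applies to dendrites admitted to analysis, in supplied order
  counts <- counts[counts$length_um >= min_length_um, , drop = FALSE]
  key <- interaction(counts$neuron_id, counts$compartment, drop = TRUE)
  within_rank <- stats::ave(seq_len(nrow(counts)), key, FUN = seq_along)
  counts <- counts[within_rank <= max_per_compartment, , drop = FALSE]
  scale <- if (per_10um) 10 else 1
  counts$density <- scale * counts$spine_count / counts$length_um
  rownames(counts) <- NULL
  counts
}

#' Classify a sample as normal, lognormal, or other
#'
#' Shapiro-Wilk tests on the raw and on the log-transformed values. The
#' sample is classed by whichever scale is consistent with normality at
#' `alpha`; when both pass, the higher W statistic wins; when neither does,
#' the class is `"other"`. Samples containing non-positive values are
#' assessed on the raw scale only.
#'
#' @param sample numeric vector, `n >= 8`.
#' @param alpha significance level for the normality tests.
#' @return list: `class` (`"normal"`, `"lognormal"`, `"other"`),
#'   `raw` and `log` Shapiro results (`log` NULL when inapplicable).
#' @export
distribution_shape <- function(sample, alpha = 0.05) {
  sample <- sample[is.finite(sample)]
  if (length(sample) < 8L)
    stop("distribution_shape needs n >= 8", call. = FALSE)
  sw_raw <- stats::shapiro.test(sample)
  sw_log <- if (all(sample > 0)) stats::shapiro.test(log(sample)) else NULL
  pass_raw <- sw_raw$p.value >= alpha
  pass_log <- !is.null(sw_log) && sw_log$p.value >= alpha
  cls <- if (pass_raw && pass_log) {
    if (sw_raw$statistic >= sw_log$statistic) "normal" else "lognormal"
  } else if (pass_raw) "normal"
  else if (pass_log) "lognormal"
  else "other"
  list(class = cls, raw = sw_raw, log = sw_log)
}

measure_is_lognormal <- function(measure_class) {
  measure_class %in% c("spine_count", "sepsc_freq", "sepsc_amp")
}

#' Two-group comparison with the lognormal transform rule
#'
#' Measures empirically established as lognormal (spine counts, sEPSC
#' frequency and amplitude) are log-transformed before testing; other
#' measures are transformed according to [distribution_shape()] when both
#' groups are large enough (`n >= 8` and all-positive), and tested raw
#' otherwise. The test is a two-tailed Student t test (pooled variance;
#' paired when `design = "paired"`). Group summaries (mean, SD, SEM, n) are
#' reported on the untransformed scale.
#'
#' @param a,b numeric samples (equal length when paired).
#' @param design `"unpaired"` or `"paired"`.
#' @param measure_class one of `"spine_count"`, `"sepsc_freq"`,
#'   `"sepsc_amp"`, `"other"`.
#' @return list of class `stat_result`: `test_name`, `transform_applied`,
#'   `statistic`, `df`, `p_two_tailed`, `group_summaries`.
#' @export
compare_groups <- function(a, b, design = c("unpaired", "paired"),
                           measure_class = c("other", "spine_count",
                                             "sepsc_freq", "sepsc_amp")) {
  design <- match.arg(design)
  measure_class <- match.arg(measure_class)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("insufficient data: each group needs n >= 2", call. = FALSE)
  if (design == "paired" && length(a) != length(b))
    stop("paired design needs equal group sizes", call. = FALSE)

  transform <- if (measure_is_lognormal(measure_class)) "log"
  else if (length(a) >= 8L && length(b) >= 8L &&
             all(a > 0) && all(b > 0) &&
             distribution_shape(c(a, b))$class == "lognormal") "log"
  else "none"
  if (transform == "log" && (any(a <= 0) || any(b <= 0)))
    stop("log transform requires positive values", call. = FALSE)
  ta <- if (transform == "log") log(a) else a
  tb <- if (transform == "log") log(b) else b

  tt <- if (design == "paired") {
    d <- tb - ta
    if (stats::sd(d) < .Machine$double.eps^0.5) {
      # degenerate constant shift: report an overflow-safe limit result
      list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
           parameter = length(d) - 1,
           p.value = if (mean(d) == 0) 1 else 0)
    } else stats::t.test(tb, ta, paired = TRUE)
  } else {
    if (stats::sd(ta) < .Machine$double.eps^0.5 &&
          stats::sd(tb) < .Machine$double.eps^0.5 &&
          mean(ta) == mean(tb))
      list(statistic = 0, parameter = length(a) + length(b) - 2, p.value = 1)
    else stats::t.test(ta, tb, var.equal = TRUE)
  }
  summ <- function(v) {
    n <- length(v)
    c(mean = mean(v), sd = stats::sd(v), sem = stats::sd(v) / sqrt(n), n = n)
  }
  structure(list(
    test_name = paste("two-tailed", design, "t test"),
    transform_applied = transform,
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_two_tailed = tt$p.value,
    group_summaries = rbind(a = summ(a), b = summ(b))),
    class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s (transform: %s)\n", x$test_name,
              x$transform_applied))
  cat(sprintf("  t(%g) = %.4g, p = %.4g\n", x$df, x$statistic,
              x$p_two_tailed))
  print(round(x$group_summaries, 4))
  invisible(x)
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Fixed-effects one-way ANOVA over all groups followed by Dunnett-adjusted
#' two-sided comparisons of every group against the reference group
#' (multivariate-t adjustment via `multcomp::glht`).
#'
#' @param groups list of numeric samples (each `n >= 2`).
#' @param reference_index index of the reference group in `groups`.
#' @return list: `F`, `df_between`, `df_within`, `p_overall`, `comparisons`
#'   (data frame: group, estimate, t, p_adjusted vs reference), `method`.
#' @export
anova_dunnett <- function(groups, reference_index = 1L) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (reference_index < 1L || reference_index > length(groups))
    stop("reference index out of range", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs n >= 2", call. = FALSE)
  gnames <- names(groups)
  if (is.null(gnames)) gnames <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(gnames, lengths(groups)),
              levels = c(gnames[reference_index],
                         gnames[-reference_index]))
  if (stats::var(y) < .Machine$double.eps)
    stop("degenerate input: zero within-group variance", call. = FALSE)
  dat <- data.frame(y = y, g = g)
  fit <- stats::aov(y ~ g, data = dat)
  an <- summary(fit)[[1L]]
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(glht_fit)
  comps <- data.frame(group = gnames[-reference_index],
                      estimate = unname(sm$test$coefficients),
                      t = unname(sm$test$tstat),
                      p_adjusted = unname(as.numeric(sm$test$pvalues)))
  list(F = an[["F value"]][1L],
       df_between = as.integer(an[["Df"]][1L]),
       df_within = as.integer(an[["Df"]][2L]),
       p_overall = an[["Pr(>F)"]][1L],
       comparisons = comps,
       method = "multivariate-t (multcomp::glht, Dunnett)")
}
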