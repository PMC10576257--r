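# Group-comparison statistics: unpaired Student's t (pooled or
# Welch-Satterthwaite), and one-way ANOVA with Tukey HSD post hoc tests.
# Backed by base R's t.test / aov / TukeyHSD behind a uniform result type.

#' Unpaired two-group comparison
#'
#' Two-sided unpaired t test at a 95% confidence interval; pooled variance
#' when `equal_variance = TRUE`, Welch-Satterthwaite otherwise (the safe
#' default when the variance-equality assumption is unverified). Optionally
#' an F test of variances can choose the variant.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param equal_variance use the pooled-variance t test.
#' @param auto_variance if `TRUE`, run an F test of variances first and use
#'   the pooled test when it does not reject at `alpha = 0.05`.
#' @param labels optional `c(name_a, name_b)`.
#' @return object of class `test_result`: `test`, `statistic`, `df`,
#'   `p_value`, `conf_int` (95% CI of mean difference a - b), `means`,
#'   `sems`, `n`.
#' @export
two_group_test <- function(a, b, equal_variance = FALSE,
                           auto_variance = FALSE,
                           labels = c("a", "b")) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  degenerate <- stats::var(a) == 0 && stats::var(b) == 0
  if (degenerate && mean(a) == mean(b)) {
    res <- structure(list(
      test = "unpaired t (degenerate: zero variance, equal means)",
      statistic = 0, df = length(a) + length(b) - 2, p_value = 1,
      conf_int = c(0, 0), means = c(mean(a), mean(b)),
      sems = c(0, 0), n = c(length(a), length(b)), labels = labels,
      degenerate = TRUE), class = "test_result")
    warning("zero variance in both groups with equal means; p = 1 by convention",
            call. = FALSE)
    return(res)
  }
  if (auto_variance) {
    vf <- stats::var.test(a, b)
    equal_variance <- vf$p.value >= 0.05
  }
  tt <- stats::t.test(a, b, var.equal = equal_variance, conf.level = 0.95)
  structure(list(
    test = if (equal_variance) "unpaired t, equal variances"
           else "unpaired t, unequal variances (Welch)",
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, conf_int = as.numeric(tt$conf.int),
    means = c(mean(a), mean(b)), sems = c(se_mean(a), se_mean(b)),
    n = c(length(a), length(b)), labels = labels, degenerate = FALSE),
    class = "test_result")
}

#' One-way ANOVA with Tukey HSD post hoc tests
#'
#' @param values numeric vector of all measurements.
#' @param groups factor/character vector of group labels (>= 3 levels, each
#'   with >= 2 values; for 2 groups use [two_group_test()]).
#' @return object of class `anova_result`: `f_statistic`, `df` (between,
#'   within), `p_value`, `group_means`, `group_sems`, and `tukey`
#'   (data.frame: `comparison`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
multi_group_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 3)
    stop("fewer than 3 groups: use two_group_test()", call. = FALSE)
  if (any(table(groups) < 2))
    stop("each group needs at least 2 values", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 0.95)$groups
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  structure(list(
    f_statistic = an[["F value"]][1],
    df = c(between = an[["Df"]][1], within = an[["Df"]][2]),
    p_value = an[["Pr(>F)"]][1],
    group_means = tapply(values, groups, mean),
    group_sems = tapply(values, groups, se_mean),
    tukey = tukey), class = "anova_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s\n  %s: mean %.4g +/- %.3g SEM (n=%d);  %s: mean %.4g +/- %.3g SEM (n=%d)\n",
              x$test, x$labels[1], x$means[1], x$sems[1], x$n[1],
              x$labels[2], x$means[2], x$sems[2], x$n[2]))
  cat(sprintf("  t = %.4g, df = %.4g, p = %.4g, 95%% CI [%.4g, %.4g]\n",
              x$statistic, x$df, x$p_value, x$conf_int[1], x$conf_int[2]))
  invisible(x)
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value))
  cat("Tukey HSD:\n")
  print(x$tukey, digits = 4)
  invisible(x)
}

#' Compare two groups of transport summaries parameter by parameter
#'
#' Runs [two_group_test()] per transport parameter on per-movie values, the
#' unit of comparison being the movie (axon). No multiplicity correction is
#' applied across parameters (each parameter is tested on its own, a caveat
#' that callers should keep in mind when reading many parameters at once).
#'
#' @param summaries_a,summaries_b data.frames of stacked per-movie
#'   `transport_summary` rows.
#' @param equal_variance,auto_variance forwarded to [two_group_test()].
#' @param labels group names.
#' @return data.frame: `parameter`, `mean_a`, `mean_b`, `sem_a`, `sem_b`,
#'   `statistic`, `df`, `p_value`.
#' @export
compare_transport_groups <- function(summaries_a, summaries_b,
                                     equal_variance = FALSE,
                                     auto_variance = FALSE,
                                     labels = c("control", "treated")) {
  params <- c("flux_antero", "flux_retro", "velocity_antero", "velocity_retro",
              "run_length_antero", "run_length_retro", "pause_duration",
              "directionality", "percent_stationary", "density")
  rows <- lapply(params, function(p) {
    va <- summaries_a[[p]]; vb <- summaries_b[[p]]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (length(va) < 2 || length(vb) < 2)
      return(data.frame(parameter = p, mean_a = NA, mean_b = NA, sem_a = NA,
                        sem_b = NA, statistic = NA, df = NA, p_value = NA))
    tr <- two_group_test(va, vb, equal_variance = equal_variance,
                         auto_variance = auto_variance, labels = labels)
    data.frame(parameter = p, mean_a = tr$means[1], mean_b = tr$means[2],
               sem_a = tr$sems[1], sem_b = tr$sems[2],
               statistic = tr$statistic, df = tr$df, p_value = tr$p_value)
  })
  do.call(rbind, rows)
}
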