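# Study-level statistics: repetition averaging, one-way repeated-measures
# ANOVA with partial eta squared, Bonferroni pairwise comparisons,
# assumption checks, percent-change arithmetic.

#' Average trial repetitions into a subjects-by-conditions table
#'
#' Gait variables are analysed as the mean across the (up to three)
#' repetitions per participant-condition; participants with an empty cell
#' are excluded listwise.
#'
#' @param df data.frame with columns `participant`, `condition`, `value` and
#'   optionally `repetition`.
#' @param conditions condition order for the output columns.
#' @return numeric matrix (participants x conditions) of cell means, with
#'   attribute `excluded` listing listwise-dropped participants.
#' @export
average_repetitions <- function(df, conditions = PHONE_CONDITIONS) {
  stopifnot(all(c("participant", "condition", "value") %in% names(df)))
  conditions <- intersect(conditions, unique(df$condition))
  parts <- unique(df$participant)
  tab <- matrix(NA_real_, nrow = length(parts), ncol = length(conditions),
                dimnames = list(as.character(parts), conditions))
  agg <- stats::aggregate(value ~ participant + condition, data = df,
                          FUN = mean)
  for (i in seq_len(nrow(agg)))
    tab[as.character(agg$participant[i]), agg$condition[i]] <- agg$value[i]
  complete <- stats::complete.cases(tab)
  excluded <- rownames(tab)[!complete]
  out <- tab[complete, , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}

#' One-way repeated-measures ANOVA from sums of squares
#'
#' Within-subjects decomposition of a subjects-by-conditions table:
#' `SS_total = SS_subject + SS_condition + SS_error`, with
#' `F = MS_condition / MS_error` on uncorrected degrees of freedom
#' (`k - 1`, `(n - 1)(k - 1)`) and partial eta squared
#' `SS_condition / (SS_condition + SS_error)`.  A Greenhouse-Geisser
#' correction of the degrees of freedom is available via `gg_correction`.
#'
#' @param table numeric matrix, participants in rows, conditions in columns;
#'   complete cases, >= 2 of each.
#' @param gg_correction apply the Greenhouse-Geisser epsilon to the degrees
#'   of freedom used for the p-value.
#' @return list of class `rm_anova`: `F`, `df_effect`, `df_error`, `p`,
#'   `partial_eta_sq`, the sums of squares, and `undefined` (TRUE when the
#'   error variance is zero and F cannot be formed).
#' @export
rm_anova <- function(table, gg_correction = FALSE) {
  table <- as.matrix(table)
  n <- nrow(table); k <- ncol(table)
  stopifnot(n >= 2L, k >= 2L, !anyNA(table))
  grand <- mean(table)
  ss_subj <- k * sum((rowMeans(table) - grand)^2)
  ss_cond <- n * sum((colMeans(table) - grand)^2)
  ss_tot <- sum((table - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  df_e <- k - 1L; df_r <- (n - 1L) * (k - 1L)
  ms_cond <- ss_cond / df_e
  ms_err <- ss_err / df_r
  if (ms_err <= .Machine$double.eps * max(1, abs(grand))^2) {
    if (ss_cond <= .Machine$double.eps * max(1, abs(grand))^2) {
      # condition-invariant data: F = 0 by convention
      return(structure(list(F = 0, df_effect = df_e, df_error = df_r, p = 1,
                            partial_eta_sq = 0, ss_condition = ss_cond,
                            ss_subject = ss_subj, ss_error = ss_err,
                            undefined = FALSE), class = "rm_anova"))
    }
    return(structure(list(F = NA_real_, df_effect = df_e, df_error = df_r,
                          p = NA_real_, partial_eta_sq = NA_real_,
                          ss_condition = ss_cond, ss_subject = ss_subj,
                          ss_error = ss_err, undefined = TRUE),
                     class = "rm_anova"))
  }
  Fval <- ms_cond / ms_err
  eps <- 1
  if (gg_correction) {
    # Greenhouse-Geisser epsilon from the double-centred covariance matrix
    S <- stats::cov(table)
    Sc <- sweep(sweep(S, 1L, rowMeans(S)), 2L, colMeans(S)) + mean(S)
    eps <- sum(diag(Sc))^2 / ((k - 1L) * sum(Sc^2))
    eps <- min(max(eps, 1 / (k - 1L)), 1)
  }
  p <- stats::pf(Fval, eps * df_e, eps * df_r, lower.tail = FALSE)
  structure(list(F = Fval, df_effect = df_e, df_error = df_r, p = p,
                 partial_eta_sq = ss_cond / (ss_cond + ss_err),
                 ss_condition = ss_cond, ss_subject = ss_subj,
                 ss_error = ss_err, gg_epsilon = eps, undefined = FALSE),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("RM-ANOVA: F(%g, %g) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
              x$df_effect, x$df_error, x$F, x$p, x$partial_eta_sq))
  invisible(x)
}

#' Bonferroni-corrected pairwise comparisons
#'
#' Paired t-tests on every condition pair, with raw p-values multiplied by
#' the number of pairs (6 for four conditions) and capped at 1.  Cohen's
#' paired-samples d is reported per pair.
#'
#' @param table subjects-by-conditions matrix.
#' @return data.frame with columns `a`, `b`, `mean_diff`, `t`, `df`,
#'   `p_raw`, `p_adj`, `cohens_d`, `flagged` (TRUE for zero-variance
#'   difference vectors, whose p-values are `NA`).
#' @export
bonferroni_pairwise <- function(table) {
  table <- as.matrix(table)
  k <- ncol(table)
  stopifnot(k >= 2L, nrow(table) >= 2L, !anyNA(table))
  pairs <- utils::combn(k, 2L)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    d <- table[, i1] - table[, i2]
    if (stats::sd(d) <= .Machine$double.eps * max(1, mean(abs(d)))) {
      return(data.frame(a = colnames(table)[i1], b = colnames(table)[i2],
                        mean_diff = mean(d), t = NA_real_,
                        df = length(d) - 1L, p_raw = NA_real_,
                        p_adj = NA_real_, cohens_d = NA_real_,
                        flagged = TRUE))
    }
    tt <- stats::t.test(table[, i1], table[, i2], paired = TRUE)
    data.frame(a = colnames(table)[i1], b = colnames(table)[i2],
               mean_diff = mean(d), t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value,
               p_adj = min(1, tt$p.value * m),
               cohens_d = mean(d) / stats::sd(d), flagged = FALSE)
  })
  do.call(rbind, rows)
}

#' Levene and Kolmogorov-Smirnov assumption checks
#'
#' Levene's test (mean-centred absolute deviations, one-way ANOVA across
#' conditions) for variance homogeneity, and per-condition one-sample KS
#' tests against a normal with the sample's own moments.
#'
#' @param table subjects-by-conditions matrix (>= 3 subjects).
#' @return list: `levene` (`F`, `df1`, `df2`, `p`) and `ks` (data.frame of
#'   per-condition `D` and `p`).
#' @export
assumption_checks <- function(table) {
  table <- as.matrix(table)
  n <- nrow(table); k <- ncol(table)
  if (n < 3L) stop("assumption_checks: need at least 3 subjects per condition")
  dev <- abs(sweep(table, 2L, colMeans(table)))
  grand <- mean(dev)
  ss_between <- n * sum((colMeans(dev) - grand)^2)
  ss_within <- sum(sweep(dev, 2L, colMeans(dev))^2)
  df1 <- k - 1L; df2 <- k * (n - 1L)
  Fv <- (ss_between / df1) / (ss_within / df2)
  lev <- list(F = Fv, df1 = df1, df2 = df2,
              p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
  cn <- colnames(table)
  if (is.null(cn)) cn <- paste0("condition", seq_len(k))
  ks <- do.call(rbind, lapply(seq_len(k), function(j) {
    x <- table[, j]
    kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    data.frame(condition = cn[j], D = unname(kt$statistic),
               p = kt$p.value)
  }))
  list(levene = lev, ks = ks)
}

#' Signed percent change of `a` relative to `b`
#'
#' `100 * (a - b) / b`, the convention used for every "A compared to B"
#' percentage in condition-comparison reporting.
#'
#' @param value_a,value_b numeric values; `value_b` must be non-zero.
#' @return signed percent change.
#' @export
#' @examples
#' percent_change(10.46, 6.27)   # +66.8
percent_change <- function(value_a, value_b) {
  if (any(value_b == 0)) stop("percent_change: reference value is zero")
  100 * (value_a - value_b) / value_b
}

#' Round a percent change for reporting
#'
#' Nearest integer, halves away from zero (the convention that reproduces
#' every checkable printed percentage).
#'
#' @param pc signed percent change.
#' @return integer-valued numeric of the same sign.
#' @export
round_percent <- function(pc) sign(pc) * floor(abs(pc) + 0.5)

#' Repetition / trial-position effect check on trial durations
#'
#' RM-ANOVA over trial position (e.g. first, mid, last) to verify that task
#' habituation or the step-position jitter did not affect completion time.
#'
#' @param durations subjects-by-positions matrix of trial durations (s).
#' @return an `rm_anova` result.
#' @export
repetition_effect_check <- function(durations) rm_anova(durations)
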