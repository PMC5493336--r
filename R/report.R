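# Condition-summary tables in the style of the published gaze/gait tables.

#' Build a condition summary table for one or more variables
#'
#' For each variable: per-condition group mean and SD, the omnibus RM-ANOVA
#' p-value and partial eta squared, and Bonferroni pairwise annotations.
#' Variables absent in a condition (the phone AOI outside read/write) are
#' reported as `"-"` in the formatted output.
#'
#' @param df long data.frame with columns `participant`, `condition`,
#'   `variable`, `value` (one row per participant-condition cell, i.e.
#'   already repetition-averaged where applicable).
#' @param conditions condition column order.
#' @return data.frame with one row per variable: `mean_<cond>`, `sd_<cond>`,
#'   `p`, `partial_eta_sq`, `n`; attribute `pairwise` holds the per-variable
#'   pairwise tables.
#' @export
build_condition_table <- function(df, conditions = PHONE_CONDITIONS) {
  stopifnot(all(c("participant", "condition", "variable", "value")
                %in% names(df)))
  vars <- unique(df$variable)
  pairwise <- list()
  rows <- lapply(vars, function(v) {
    sub <- df[df$variable == v & !is.na(df$value), , drop = FALSE]
    conds <- intersect(conditions, unique(sub$condition))
    row <- list(variable = v)
    for (cn in conditions) {
      x <- sub$value[sub$condition == cn]
      row[[paste0("mean_", cn)]] <- if (length(x)) mean(x) else NA_real_
      row[[paste0("sd_", cn)]] <-
        if (length(x) >= 2L) stats::sd(x) else if (length(x)) 0 else NA_real_
    }
    tab <- tryCatch(average_repetitions(
      data.frame(participant = sub$participant, condition = sub$condition,
                 value = sub$value), conds), error = function(e) NULL)
    if (!is.null(tab) && nrow(tab) >= 2L && ncol(tab) >= 2L) {
      an <- rm_anova(tab)
      row$p <- an$p; row$partial_eta_sq <- an$partial_eta_sq
      row$n <- nrow(tab)
      pairwise[[v]] <<- bonferroni_pairwise(tab)
    } else {
      row$p <- NA_real_; row$partial_eta_sq <- NA_real_
      row$n <- if (is.null(tab)) 0L else nrow(tab)
    }
    as.data.frame(row)
  })
  out <- do.call(rbind, rows)
  attr(out, "pairwise") <- pairwise
  out
}

#' Format a condition table as text
#'
#' Mean (SD) per condition with `-` for absent cells, plus p and partial eta
#' squared columns.
#'
#' @param tab result of [build_condition_table()].
#' @param conditions condition column order.
#' @param digits digits for means/SDs.
#' @return character vector of formatted lines (also printed).
#' @export
format_condition_table <- function(tab, conditions = PHONE_CONDITIONS,
                                   digits = 2) {
  fmt_cell <- function(m, s) {
    if (is.na(m)) "-" else sprintf("%.*f (%.*f)", digits, m, digits,
                                   if (is.na(s)) 0 else s)
  }
  header <- c("variable", conditions, "p", "eta_p^2")
  lines <- vapply(seq_len(nrow(tab)), function(i) {
    cells <- vapply(conditions, function(cn)
      fmt_cell(tab[[paste0("mean_", cn)]][i], tab[[paste0("sd_", cn)]][i]),
      character(1))
    paste(c(tab$variable[i], cells,
            ifelse(is.na(tab$p[i]), "-", sprintf("%.4f", tab$p[i])),
            ifelse(is.na(tab$partial_eta_sq[i]), "-",
                   sprintf("%.3f", tab$partial_eta_sq[i]))),
          collapse = "\t")
  }, character(1))
  out <- c(paste(header, collapse = "\t"), lines)
  cat(out, sep = "\n")
  invisible(out)
}
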