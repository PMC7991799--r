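# Treatment-versus-control summaries: velocity ratios, two-sample tests,
# and dose-response tabulation. Statistical tests are delegated to the
# standard routines (stats::t.test, stats::wilcox.test).

#' Velocity ratio in percent
#'
#' `100 * v_treated / v_control`. Ratios below 100 indicate slowdown; the
#' ratio may be negative when the treated wound edge retracts.
#'
#' @param v_treated Treated-condition edge velocity, um/h.
#' @param v_control Control edge velocity, um/h (non-zero).
#' @return Ratio in percent.
#' @export
velocity_ratio <- function(v_treated, v_control) {
  if (any(v_control == 0)) .stopf("control velocity must be non-zero")
  100 * v_treated / v_control
}

#' Summarise one condition's replicate velocities
#'
#' @param replicate_v Numeric vector of per-replicate edge velocities, um/h.
#' @param label Condition label.
#' @return A `condition_summary` with `label`, `mean_v_um_per_h`, `sem`,
#'   `n`, `replicate_v`.
#' @export
condition_summary <- function(replicate_v, label = "condition") {
  if (length(replicate_v) < 1) .stopf("empty replicate set")
  structure(list(label = label, mean_v_um_per_h = mean(replicate_v),
                 sem = if (length(replicate_v) > 1)
                   stats::sd(replicate_v) / sqrt(length(replicate_v)) else NA_real_,
                 n = length(replicate_v), replicate_v = replicate_v),
            class = "condition_summary")
}

#' Compare treated vs control replicate velocities
#'
#' The ratio is computed from the group means; the p-value comes from the
#' selected standard two-sample test. With fewer than 2 replicates in either
#' group only the ratio is reported (`p_value = NA`).
#'
#' @param treated,control Numeric vectors of replicate velocities (um/h).
#' @param test `"t"` (Student, pooled variance; the default), `"welch"`, or
#'   `"wilcoxon"`.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param labels Character length-2 labels for the two groups.
#' @return A `treatment_effect` with `treated`, `control`
#'   (condition summaries), `ratio_pct`, `p_value`, `significant`.
#' @export
compare_conditions <- function(treated, control,
                               test = c("t", "welch", "wilcoxon"),
                               alpha = 0.05,
                               labels = c("treated", "control")) {
  test <- match.arg(test)
  if (length(treated) == 0 || length(control) == 0) .stopf("empty group")
  ts <- condition_summary(treated, labels[1])
  cs <- condition_summary(control, labels[2])
  ratio <- velocity_ratio(ts$mean_v_um_per_h, cs$mean_v_um_per_h)
  p <- NA_real_
  if (length(treated) >= 2 && length(control) >= 2) {
    p <- switch(test,
      t = stats::t.test(treated, control, var.equal = TRUE)$p.value,
      welch = stats::t.test(treated, control)$p.value,
      wilcoxon = stats::wilcox.test(treated, control, exact = FALSE)$p.value)
  }
  structure(list(treated = ts, control = cs, ratio_pct = ratio,
                 p_value = p, significant = !is.na(p) && p < alpha),
            class = "treatment_effect")
}

#' @export
print.treatment_effect <- function(x, ...) {
  cat(sprintf("<treatment_effect> %s vs %s: ratio %.2f%% (p = %.4g%s)\n",
              x$treated$label, x$control$label, x$ratio_pct, x$p_value,
              if (isTRUE(x$significant)) ", significant" else ""))
  invisible(x)
}

#' Significance stars
#'
#' `**` for p < 0.01, `*` for p < 0.05, `ns` otherwise.
#' @param p P-value(s).
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Tabulate treatment effects across doses
#'
#' @param effects Named list of `treatment_effect` objects; names are dose
#'   labels parsed as numbers (e.g. `"300"` nM). Duplicate doses are an
#'   error.
#' @return Data frame with columns `dose`, `ratio_pct`, `p_value`, `stars`,
#'   sorted by ascending dose. No monotonicity is imposed: dose-response
#'   curves of motility inhibitors are frequently non-monotonic.
#' @export
dose_response_table <- function(effects) {
  if (length(effects) < 1) .stopf("no doses")
  doses <- suppressWarnings(as.numeric(names(effects)))
  if (anyNA(doses)) .stopf("dose labels must be numeric")
  if (anyDuplicated(doses)) .stopf("duplicate dose labels")
  df <- data.frame(dose = doses,
                   ratio_pct = vapply(effects, function(e) e$ratio_pct, numeric(1)),
                   p_value = vapply(effects, function(e) e$p_value, numeric(1)),
                   stringsAsFactors = FALSE, row.names = NULL)
  df$stars <- significance_stars(df$p_value)
  df <- df[order(df$dose), , drop = FALSE]
  rownames(df) <- NULL
  df
}
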