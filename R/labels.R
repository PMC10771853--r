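#' Classify therapy response from DAS28 scores
#'
#' Applies the EULAR-style binary response rule used throughout the pipeline:
#' a patient is a responder when the follow-up DAS28 is below 3.2 or the
#' decrease from baseline is at least 1.2 points, and a non-responder when the
#' follow-up DAS28 exceeds 5.1 or the decrease is below 0.6 points. The two
#' rules can both fire (e.g. a large drop that still leaves DAS28 above 5.1);
#' such cases are surfaced as `"conflict"` rather than silently resolved, and
#' cases where neither rule fires are `"indeterminate"`.
#'
#' Boundary semantics follow the printed criteria exactly: "decrease of at
#' least 1.2" is `>= 1.2`, "decrease of < 0.6" is strict, and the DAS28 cut
#' points 3.2 and 5.1 are strict inequalities.
#'
#' @param baseline,followup DAS28 scores on the 1-10 composite scale, both in
#'   \[0, 10\]; vectorized.
#' @return character vector with values `"responder"`, `"non_responder"`,
#'   `"indeterminate"` or `"conflict"`.
#' @seealso [label_response()] for the record-keeping variant.
#' @export
classify_das28 <- function(baseline, followup) {
  .assert(length(baseline) == length(followup),
          "baseline and followup must have equal length")
  .assert(all(is.finite(baseline)) && all(is.finite(followup)),
          "DAS28 scores must be finite")
  if (any(baseline < 0 | baseline > 10 | followup < 0 | followup > 10)) {
    stop("DAS28 scores must lie in [0, 10]", call. = FALSE)
  }
  dec <- baseline - followup
  r  <- (followup < 3.2) | (dec >= 1.2)
  nr <- (followup > 5.1) | (dec < 0.6)
  out <- rep("indeterminate", length(baseline))
  out[r & !nr] <- "responder"
  out[!r & nr] <- "non_responder"
  out[r & nr]  <- "conflict"
  out
}

#' Response calls with full bookkeeping
#'
#' @param sample_id sample identifiers (optional).
#' @inheritParams classify_das28
#' @return data.frame with columns `sample_id`, `baseline`, `followup`,
#'   `decrease` and `label`.
#' @export
label_response <- function(baseline, followup, sample_id = NULL) {
  lab <- classify_das28(baseline, followup)
  if (is.null(sample_id)) sample_id <- seq_along(baseline)
  data.frame(sample_id = sample_id, baseline = baseline, followup = followup,
             decrease = baseline - followup, label = lab,
             stringsAsFactors = FALSE)
}

.fmt_num <- function(x, digits = 1) formatC(x, format = "f", digits = digits)

#' Cohort characteristics table with group comparisons
#'
#' Summarizes baseline variables by response group in the conventional
#' clinical-table style: categorical variables as n (%), normally distributed
#' continuous variables as mean (SD) compared by the independent-samples
#' pooled-variance t-test, and skewed continuous variables as median (IQR)
#' compared by the Mann-Whitney U test (exact when the smaller group has at
#' most 8 untied observations, normal approximation otherwise). Categorical
#' variables are compared by the chi-square test without continuity
#' correction by default. Missing values are dropped per variable and the
#' effective n reported.
#'
#' @param sheet sample sheet containing a `response` column with values
#'   `"responder"`/`"non_responder"` plus the variables to summarize.
#' @param variable_spec data.frame with columns `variable` and `type`, where
#'   type is one of `"categorical"`, `"continuous_normal"`,
#'   `"continuous_skewed"`.
#' @param correct logical; apply Yates continuity correction to chi-square
#'   tests (default FALSE).
#' @param alpha significance flag threshold (two-sided), default 0.05; a
#'   p-value less than or equal to alpha is flagged significant.
#' @return data.frame, one row per variable: summaries per group, effective
#'   group sizes, test used, p-value, significance flag.
#' @export
cohort_table <- function(sheet, variable_spec, correct = FALSE, alpha = 0.05) {
  .assert(all(c("variable", "type") %in% names(variable_spec)),
          "variable_spec needs columns 'variable' and 'type'")
  .assert("response" %in% names(sheet), "sheet needs a 'response' column")
  grp <- sheet$response
  .assert(all(grp %in% c("responder", "non_responder")),
          "response column must be responder/non_responder")
  .assert(min(table(grp)) >= 2, "each response group needs at least 2 samples")
  rows <- lapply(seq_len(nrow(variable_spec)), function(i) {
    v <- variable_spec$variable[i]
    ty <- variable_spec$type[i]
    if (!v %in% names(sheet)) stop("unknown variable: ", v, call. = FALSE)
    x <- sheet[[v]]
    keep <- !is.na(x)
    xr <- x[keep & grp == "responder"]
    xn <- x[keep & grp == "non_responder"]
    note <- ""
    if (ty == "categorical") {
      # binary indicators (0/1 numeric or logical)
      xr <- as.integer(as.numeric(xr) != 0)
      xn <- as.integer(as.numeric(xn) != 0)
      sr <- sprintf("%d (%s%%)", sum(xr), .fmt_num(100 * mean(xr)))
      sn <- sprintf("%d (%s%%)", sum(xn), .fmt_num(100 * mean(xn)))
      tab <- rbind(c(sum(xr), length(xr) - sum(xr)),
                   c(sum(xn), length(xn) - sum(xn)))
      p <- tryCatch(
        suppressWarnings(chisq.test(tab, correct = correct)$p.value),
        error = function(e) NA_real_)
      test <- "chi-square"
    } else if (ty == "continuous_normal") {
      sr <- sprintf("%s (%s)", .fmt_num(mean(xr)), .fmt_num(sd(xr)))
      sn <- sprintf("%s (%s)", .fmt_num(mean(xn)), .fmt_num(sd(xn)))
      if (sd(c(xr, xn)) == 0) {
        p <- NA_real_; note <- "zero variance, test skipped"
      } else {
        p <- t.test(xr, xn, var.equal = TRUE)$p.value
      }
      test <- "t-test"
    } else if (ty == "continuous_skewed") {
      qr <- quantile(xr, c(0.25, 0.75)); qn <- quantile(xn, c(0.25, 0.75))
      sr <- sprintf("%s (%s-%s)", .fmt_num(median(xr)),
                    .fmt_num(qr[1]), .fmt_num(qr[2]))
      sn <- sprintf("%s (%s-%s)", .fmt_num(median(xn)),
                    .fmt_num(qn[1]), .fmt_num(qn[2]))
      if (sd(c(xr, xn)) == 0) {
        p <- NA_real_; note <- "zero variance, test skipped"
      } else {
        exact <- min(length(xr), length(xn)) <= 8 &&
          !any(duplicated(c(xr, xn)))
        p <- suppressWarnings(
          wilcox.test(xr, xn, exact = exact, correct = !exact)$p.value)
      }
      test <- "Mann-Whitney U"
    } else {
      stop("unknown variable type: ", ty, call. = FALSE)
    }
    data.frame(variable = v, type = ty,
               responders = sr, non_responders = sn,
               n_responders = length(xr), n_non_responders = length(xn),
               test = test, p_value = p,
               significant = !is.na(p) & p <= alpha,
               note = note, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
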