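#' Build a covariate-adjusted design matrix for differential methylation
#'
#' Columns: intercept, a binary response indicator (1 = responder), and the
#' requested clinical covariates. `age` enters as years; `sex` is coded as a
#' male indicator (`sexM`); `smoking` and `mtx` (concomitant methotrexate) are
#' 0/1 indicators taken from the sheet. The design must be full column rank;
#' constant or collinear columns raise an error.
#'
#' @param sheet sample sheet with a `response` column and the requested
#'   covariates, rows in the sample order of the methylation matrices.
#' @param covariates character vector among `"age"`, `"sex"`, `"smoking"`,
#'   `"mtx"`; empty for a response-only design.
#' @return numeric design matrix (samples x columns) with rownames from
#'   `sample_id`.
#' @export
build_design <- function(sheet, covariates = character()) {
  .assert(all(c("sample_id", "response") %in% names(sheet)),
          "sheet needs sample_id and response columns")
  .assert(all(sheet$response %in% c("responder", "non_responder")),
          "response must be responder/non_responder")
  known <- c("age", "sex", "smoking", "mtx")
  bad <- setdiff(covariates, known)
  .assert(length(bad) == 0,
          paste("unknown covariates:", paste(bad, collapse = ", ")))
  X <- cbind("(Intercept)" = 1,
             response = as.numeric(sheet$response == "responder"))
  for (cv in covariates) {
    val <- sheet[[cv]]
    if (is.null(val)) stop("covariate missing from sheet: ", cv, call. = FALSE)
    if (anyNA(val)) {
      stop("missing values for covariate '", cv, "' in samples: ",
           paste(sheet$sample_id[is.na(val)], collapse = ", "), call. = FALSE)
    }
    col <- if (cv == "sex") as.numeric(val == "M") else as.numeric(val)
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- if (cv == "sex") "sexM" else cv
  }
  rownames(X) <- sheet$sample_id
  if (qr(X)$rank < ncol(X)) {
    const <- colnames(X)[-1][apply(X[, -1, drop = FALSE], 2, sd) == 0]
    stop("design matrix is rank deficient",
         if (length(const)) paste0(" (constant columns: ",
                                   paste(const, collapse = ", "), ")"),
         call. = FALSE)
  }
  X
}

#' Per-CpG covariate-adjusted differential methylation
#'
#' Fits, for every probe, an ordinary least-squares regression of the M-value
#' on the design matrix and tests the response coefficient with a t-test on
#' the residual degrees of freedom. Each probe uses its own residual variance
#' (no moderation across probes). The beta-scale group difference
#' (mean beta in responders minus mean beta in non-responders) is reported
#' alongside for interpretation on the percentage-methylation scale.
#'
#' Probes with zero residual variance and zero effect (e.g. constant across
#' all samples) are flagged and reported with t = 0, p = 1.
#'
#' @param m_matrix probes x samples M-value matrix.
#' @param design design matrix from [build_design()], rows aligned with the
#'   matrix columns.
#' @param beta_matrix probes x samples beta matrix on the same probes/samples,
#'   used only for the delta-methylation column; optional.
#' @return data.frame: `probe_id`, `coef` (response effect on the M scale),
#'   `se`, `t`, `p_value`, `delta_meth`, `df`, `zero_variance`.
#' @export
fit_dm <- function(m_matrix, design, beta_matrix = NULL) {
  .assert(is.matrix(m_matrix), "m_matrix must be a matrix")
  .assert(ncol(m_matrix) == nrow(design),
          "sample count of m_matrix and design differ")
  if (!is.null(rownames(design)) && !is.null(colnames(m_matrix)) &&
      !identical(colnames(m_matrix), rownames(design))) {
    stop("sample order of m_matrix and design differ", call. = FALSE)
  }
  n <- nrow(design); p <- ncol(design)
  df <- n - p
  .assert(df >= 1, "residual degrees of freedom must be at least 1")
  XtXi <- solve(crossprod(design))
  H <- design %*% XtXi                       # n x p
  coefs <- m_matrix %*% H                    # probes x p
  fitted <- coefs %*% t(design)
  rss <- rowSums((m_matrix - fitted)^2)
  sigma2 <- rss / df
  j <- which(colnames(design) == "response")
  .assert(length(j) == 1, "design must contain a 'response' column")
  b <- coefs[, j]
  se <- sqrt(sigma2 * XtXi[j, j])
  zerovar <- sigma2 < 1e-24 & abs(b) < 1e-12
  tval <- ifelse(zerovar, 0, b / ifelse(se > 0, se, NA_real_))
  pval <- ifelse(zerovar, 1, 2 * pt(-abs(tval), df))
  dm <- rep(NA_real_, nrow(m_matrix))
  if (!is.null(beta_matrix)) {
    .assert(identical(dim(beta_matrix), dim(m_matrix)),
            "beta_matrix and m_matrix must have identical shape")
    resp <- design[, j] == 1
    dm <- rowMeans(beta_matrix[, resp, drop = FALSE]) -
      rowMeans(beta_matrix[, !resp, drop = FALSE])
  }
  data.frame(probe_id = rownames(m_matrix), coef = b, se = se, t = tval,
             p_value = pval, delta_meth = dm, df = df,
             zero_variance = zerovar, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Differential-methylation results table in reporting format
#'
#' Joins a [fit_dm()] result with manifest annotation and adds a direction
#' column: "Hypermethylation" when the responder-minus-non-responder beta
#' difference is positive, "Hypomethylation" otherwise.
#'
#' @param dm result of [fit_dm()].
#' @param manifest probe manifest with `probe_id`, `chr`, `pos`, `gene`,
#'   `feature`.
#' @param bh add a Benjamini-Hochberg adjusted p-value column (default FALSE;
#'   nominal p-values are the primary output).
#' @return data.frame ordered as the input dm.
#' @export
dm_table <- function(dm, manifest, bh = FALSE) {
  idx <- match(dm$probe_id, manifest$probe_id)
  out <- data.frame(
    probe_id = dm$probe_id,
    chr = manifest$chr[idx], pos = manifest$pos[idx],
    delta_meth = dm$delta_meth, p_value = dm$p_value,
    gene = manifest$gene[idx], feature = manifest$feature[idx],
    direction = ifelse(dm$delta_meth > 0, "Hypermethylation",
                       "Hypomethylation"),
    stringsAsFactors = FALSE
  )
  if (bh) out$q_value <- p.adjust(dm$p_value, method = "BH")
  out
}

#' Covariate robustness of a probe panel
#'
#' Refits a panel of probes with and without the clinical covariates and
#' reports both p-values per probe plus how many remain below 0.05 after
#' adjustment — the check that a response association is not explained by
#' concomitant methotrexate use, smoking, sex or age.
#'
#' @param panel probe ids to test (may be empty).
#' @param m_matrix probes x samples M-value matrix containing the panel.
#' @param sheet sample sheet aligned with the matrix columns.
#' @param covariates covariates for the adjusted design.
#' @return data.frame `probe_id`, `p_unadjusted`, `p_adjusted`, with
#'   attributes `n_below_unadjusted` and `n_below_adjusted` (count of p < 0.05).
#' @export
covariate_robustness <- function(panel, m_matrix, sheet,
                                 covariates = c("age", "sex", "smoking", "mtx")) {
  if (length(panel) == 0) {
    out <- data.frame(probe_id = character(0), p_unadjusted = numeric(0),
                      p_adjusted = numeric(0), stringsAsFactors = FALSE)
    attr(out, "n_below_unadjusted") <- 0L
    attr(out, "n_below_adjusted") <- 0L
    return(out)
  }
  missing <- setdiff(panel, rownames(m_matrix))
  .assert(length(missing) == 0,
          paste("panel probes absent from matrix:",
                paste(head(missing, 5), collapse = ", ")))
  m <- m_matrix[panel, , drop = FALSE]
  d0 <- build_design(sheet)
  d1 <- build_design(sheet, covariates)
  f0 <- fit_dm(m, d0)
  f1 <- fit_dm(m, d1)
  out <- data.frame(probe_id = panel, p_unadjusted = f0$p_value,
                    p_adjusted = f1$p_value, stringsAsFactors = FALSE)
  attr(out, "n_below_unadjusted") <- sum(f0$p_value < 0.05)
  attr(out, "n_below_adjusted") <- sum(f1$p_value < 0.05)
  out
}
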