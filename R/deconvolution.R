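#' Estimate leukocyte proportions by constrained least squares
#'
#' Reference-based cell-mixture deconvolution: for each sample, the vector of
#' betas over the deconvolution probes is projected onto the reference
#' profiles by non-negative least squares, `min_w ||R w - b||^2` subject to
#' `w >= 0`. The sum-to-one constraint is not imposed during optimization;
#' normalized proportions are derived from the raw weights afterwards. On
#' noiseless mixtures the raw weights already sum to one.
#'
#' @param betas beta matrix over the deconvolution probes (probes x samples),
#'   probe set and order identical to `references`.
#' @param references probes x 6 reference profile matrix (see
#'   [generate_reference_profiles()] / [read_reference_profiles()]).
#' @return object of class `cell_proportions`: list with `raw` and
#'   `proportions` (samples x cell types matrices) and `residual_norm`.
#' @export
estimate_proportions <- function(betas, references) {
  .assert(is.matrix(betas) && is.matrix(references),
          "betas and references must be matrices")
  if (!identical(rownames(betas), rownames(references))) {
    stop("probe sets of betas and references must be identical and aligned",
         call. = FALSE)
  }
  if (qr(references)$rank < ncol(references)) {
    stop("reference matrix is rank-deficient; cell types are not separable",
         call. = FALSE)
  }
  n <- ncol(betas)
  raw <- matrix(NA_real_, n, ncol(references),
                dimnames = list(colnames(betas), colnames(references)))
  rn <- numeric(n)
  for (j in seq_len(n)) {
    fit <- pracma::lsqnonneg(references, betas[, j])
    raw[j, ] <- fit$x
    rn[j] <- sqrt(fit$resid.norm)
  }
  tot <- rowSums(raw)
  props <- raw / ifelse(tot > 0, tot, 1)
  structure(list(raw = raw, proportions = props, residual_norm = rn),
            class = "cell_proportions")
}

#' @export
print.cell_proportions <- function(x, ...) {
  cat("Cell proportion estimates for", nrow(x$proportions), "samples\n")
  print(round(colMeans(x$proportions), 3))
  invisible(x)
}

#' Write cell-proportion estimates as CSV (raw and normalized blocks)
#' @param props a `cell_proportions` object.
#' @param path output path.
#' @export
write_proportions <- function(props, path) {
  raw <- props$raw; colnames(raw) <- paste0("raw_", colnames(raw))
  out <- data.frame(sample_id = rownames(props$proportions),
                    props$proportions, raw, check.names = FALSE)
  data.table::fwrite(out, path, sep = ",", quote = FALSE)
  invisible(path)
}

#' Compare estimated cell proportions between response groups
#'
#' Two-way ANOVA of proportion on response group and cell type with the
#' sample as the whole-plot error stratum (a split-plot / repeated-measures
#' layout): every sample contributes all six cell types, so the group main
#' effect is tested against between-sample variation and the cell-type and
#' group-by-cell-type effects against the within-sample residual. By default
#' the response is variance-stabilized by the arcsine-square-root transform,
#' which equalizes the spread of minor and dominant cell types and keeps the
#' tests calibrated on compositional data; per-cell-type group contrasts
#' (pooled-variance t-tests on the untransformed proportions) are reported as
#' a secondary output.
#'
#' @param props a `cell_proportions` object.
#' @param labels response label per sample (`"responder"`/`"non_responder"`),
#'   aligned with the rows of the proportion matrix.
#' @param use `"proportions"` (normalized, default) or `"raw"` weights.
#' @param stabilize apply the arcsine-square-root transform (default TRUE).
#' @return list with `anova` (term, stratum, sum of squares, df, F, p) and
#'   `contrasts` (per-cell-type mean difference and t-test p-value).
#' @export
compare_proportions <- function(props, labels,
                                use = c("proportions", "raw"),
                                stabilize = TRUE) {
  use <- match.arg(use)
  P <- props[[use]]
  .assert(length(labels) == nrow(P), "one label per sample required")
  .assert(all(labels %in% c("responder", "non_responder")),
          "labels must be responder/non_responder")
  if (min(table(labels)) < 2) {
    stop("each response group needs at least 2 samples", call. = FALSE)
  }
  resp <- if (stabilize) asin(sqrt(.clamp(as.vector(P), 0, 1)))
          else as.vector(P)
  long <- data.frame(
    y = resp,
    celltype = factor(rep(colnames(P), each = nrow(P)), levels = colnames(P)),
    group = factor(rep(labels, ncol(P)),
                   levels = c("non_responder", "responder")),
    sample = factor(rep(seq_len(nrow(P)), ncol(P)))
  )
  fit <- stats::aov(y ~ group * celltype + Error(sample), data = long)
  s <- summary(fit)
  between <- s[["Error: sample"]][[1]]
  within <- s[["Error: Within"]][[1]]
  strip <- function(tab, stratum) {
    data.frame(term = trimws(rownames(tab)), stratum = stratum,
               sumsq = tab[["Sum Sq"]], df = tab[["Df"]],
               F = tab[["F value"]], p_value = tab[["Pr(>F)"]],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  an <- rbind(strip(between, "between-sample"), strip(within, "within-sample"))
  contrasts <- do.call(rbind, lapply(colnames(P), function(ct) {
    xr <- P[labels == "responder", ct]
    xn <- P[labels == "non_responder", ct]
    p <- if (sd(c(xr, xn)) == 0) NA_real_ else
      t.test(xr, xn, var.equal = TRUE)$p.value
    data.frame(celltype = ct, mean_responder = mean(xr),
               mean_non_responder = mean(xn),
               difference = mean(xr) - mean(xn), p_value = p,
               stringsAsFactors = FALSE)
  }))
  list(anova = an, contrasts = contrasts)
}
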