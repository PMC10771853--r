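#' Annotate probes to nearest genes within 20 kb
#'
#' A probe is assigned to a gene when it lies inside the gene body or within
#' `max_distance` base pairs (inclusive) of either boundary. When several
#' genes qualify, the smallest probe-to-gene distance wins (0 inside the
#' body); equal distances (e.g. a probe inside two overlapping genes) are
#' broken by the distance to the gene midpoint, then by lexicographic gene
#' symbol, so annotation is deterministic. Probes with no gene in range keep
#' an absent (`NA`) annotation.
#'
#' @param manifest probe manifest with `probe_id`, `chr`, `pos`.
#' @param gene_table data.frame with `gene`, `chr`, `start`, `end`
#'   (1-based inclusive).
#' @param max_distance maximum probe-to-boundary distance in bp, default 20000.
#' @return the manifest with `gene` and `gene_distance` columns (re)assigned.
#' @export
annotate_probes <- function(manifest, gene_table, max_distance = 20000) {
  .assert(all(c("gene", "chr", "start", "end") %in% names(gene_table)),
          "gene_table needs columns gene, chr, start, end")
  if (any(gene_table$start > gene_table$end)) {
    bad <- gene_table$gene[gene_table$start > gene_table$end]
    stop("malformed gene intervals (start > end): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- manifest
  out$gene <- NA_character_
  out$gene_distance <- NA_real_
  for (ch in unique(manifest$chr)) {
    gi <- gene_table[gene_table$chr == ch, , drop = FALSE]
    if (nrow(gi) == 0) next
    pi <- which(manifest$chr == ch)
    pos <- manifest$pos[pi]
    # distance of each probe (rows) to each gene (cols); 0 inside the body
    D <- outer(pos, gi$start, function(p, s) pmax(s - p, 0)) +
         outer(pos, gi$end,   function(p, e) pmax(p - e, 0))
    Dmid <- abs(outer(pos, (gi$start + gi$end) / 2, "-"))
    for (r in seq_along(pi)) {
      cand <- which(D[r, ] <= max_distance)
      if (length(cand) == 0) next
      o <- order(D[r, cand], Dmid[r, cand], gi$gene[cand])
      best <- cand[o[1]]
      out$gene[pi[r]] <- gi$gene[best]
      out$gene_distance[pi[r]] <- D[r, best]
    }
  }
  out
}

# Kost-McDermott polynomial approximation to the covariance between two
# correlated -2 ln p statistics, clipped into [0, 4]
.kost_cov <- function(rho) {
  pmin(4, pmax(0, 3.263 * rho + 0.710 * rho^2 + 0.027 * rho^3))
}

#' Combine correlated p-values by Brown's method
#'
#' Extends Fisher's combination statistic `psi = -2 sum(ln p)` to correlated
#' tests: the mean of psi is `2k` and its variance is `4k` plus twice the sum
#' of pairwise covariances of the -2 ln p terms, approximated from the score
#' correlations by the Kost-McDermott polynomial. psi is then referred to a
#' scaled chi-square with effective degrees of freedom
#' `f = 2 E^2 / Var` and scale `c = Var / (2 E)`. With zero correlations this
#' reduces exactly to Fisher's method; with `k = 1` it returns the input
#' p-value.
#'
#' @param pvalues vector of p-values in (0, 1\].
#' @param correlations k x k symmetric correlation matrix of the underlying
#'   scores (unit diagonal); `NULL` means independence.
#' @return list of class `gene_aggregate`: `k`, `psi`, `expected`, `variance`,
#'   `scale`, `df`, `p_value`.
#' @export
brown_combine <- function(pvalues, correlations = NULL) {
  k <- length(pvalues)
  .assert(k >= 1, "at least one p-value required")
  if (any(pvalues <= 0)) {
    stop("p-values of 0 cannot be log-combined; floor them at a small ",
         "positive value (e.g. 1e-300) first", call. = FALSE)
  }
  .assert(all(pvalues <= 1), "p-values must lie in (0,1]")
  if (is.null(correlations)) correlations <- diag(k)
  .assert(is.matrix(correlations) && all(dim(correlations) == k),
          "correlation matrix dimension must match the number of p-values")
  .assert(max(abs(correlations - t(correlations))) < 1e-8,
          "correlation matrix must be symmetric")
  .assert(max(abs(diag(correlations) - 1)) < 1e-8,
          "correlation matrix must have unit diagonal")
  if (k > 1) {
    ev <- eigen(correlations, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      warning("correlation matrix is not positive semi-definite; ",
              "pairwise covariances are used as-is")
    }
  }
  psi <- -2 * sum(log(pvalues))
  E <- 2 * k
  cov_sum <- if (k > 1) sum(.kost_cov(correlations[upper.tri(correlations)]))
             else 0
  v <- 4 * k + 2 * cov_sum
  cc <- v / (2 * E)
  f <- 2 * E^2 / v
  structure(list(k = k, psi = psi, expected = E, variance = v, scale = cc,
                 df = f, p_value = pchisq(psi / cc, df = f,
                                          lower.tail = FALSE)),
            class = "gene_aggregate")
}

#' @export
print.gene_aggregate <- function(x, ...) {
  cat(sprintf("Brown combination of %d p-values: psi = %.4g, eff. df = %.3g, p = %.4g\n",
              x$k, x$psi, x$df, x$p_value))
  invisible(x)
}

#' Gene-level p-values from per-CpG results
#'
#' For each requested gene, gathers its annotated probes, estimates pairwise
#' Pearson correlations of the probe M-values across samples, and combines
#' the per-probe p-values by [brown_combine()]. Genes with no annotated probe
#' are reported as absent rather than raising an error.
#'
#' @param dm per-probe results from [fit_dm()] (needs `probe_id`, `p_value`).
#' @param annotation annotated manifest from [annotate_probes()] (needs
#'   `probe_id`, `gene`).
#' @param m_matrix probes x samples M-value matrix for correlation estimation.
#' @param genes gene symbols to aggregate.
#' @param method correlation method, `"pearson"` (default) or `"spearman"`.
#' @return data.frame: `gene`, `n_probes`, `psi`, `df_eff`, `p_value`.
#' @export
gene_level_scan <- function(dm, annotation, m_matrix, genes,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  rows <- lapply(genes, function(g) {
    ids <- annotation$probe_id[!is.na(annotation$gene) & annotation$gene == g]
    ids <- intersect(ids, dm$probe_id)
    if (length(ids) == 0) {
      return(data.frame(gene = g, n_probes = 0L, psi = NA_real_,
                        df_eff = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    p <- dm$p_value[match(ids, dm$probe_id)]
    cors <- if (length(ids) > 1) {
      cor(t(m_matrix[ids, , drop = FALSE]), method = method)
    } else NULL
    agg <- brown_combine(p, cors)
    data.frame(gene = g, n_probes = agg$k, psi = agg$psi, df_eff = agg$df,
               p_value = agg$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Regional delta-methylation profile of a gene with loess smoothing
#'
#' Collects the per-probe beta-scale group differences across a gene region,
#' orders them by genomic position, and fits a degree-1 loess curve evaluated
#' with pointwise standard errors on a 200-point grid spanning the probe
#' positions. With fewer than 3 probes the points are returned and smoothing
#' is skipped with a notice.
#'
#' @param gene gene symbol.
#' @param dm per-probe results from [fit_dm()] (needs `delta_meth`).
#' @param annotation annotated manifest (needs `probe_id`, `gene`, `pos`).
#' @param span loess span in (0, 1\], default 0.75.
#' @param first_exon optional numeric `c(start, end)` interval passed through
#'   for plotting annotation.
#' @param grid_points number of grid points, default 200.
#' @return list of class `regional_profile`: `gene`, `points` (data.frame
#'   pos/delta_meth/probe_id), `curve` (data.frame pos/fit/se or NULL),
#'   `first_exon`.
#' @export
regional_profile <- function(gene, dm, annotation, span = 0.75,
                             first_exon = NULL, grid_points = 200L) {
  .assert(span > 0 && span <= 1, "span must lie in (0,1]")
  ids <- annotation$probe_id[!is.na(annotation$gene) & annotation$gene == gene]
  ids <- intersect(ids, dm$probe_id)
  pos <- annotation$pos[match(ids, annotation$probe_id)]
  delta <- dm$delta_meth[match(ids, dm$probe_id)]
  o <- order(pos)
  pts <- data.frame(probe_id = ids[o], pos = pos[o], delta_meth = delta[o],
                    stringsAsFactors = FALSE)
  curve <- NULL
  if (nrow(pts) >= 3) {
    fit <- loess(delta_meth ~ pos, data = pts, span = span, degree = 1,
                 family = "gaussian",
                 control = loess.control(surface = "direct"))
    grid <- seq(min(pts$pos), max(pts$pos), length.out = grid_points)
    pr <- predict(fit, newdata = data.frame(pos = grid), se = TRUE)
    curve <- data.frame(pos = grid, fit = pr$fit, se = pr$se.fit)
  } else {
    message("gene ", gene, " has fewer than 3 probes; smoothing skipped")
  }
  structure(list(gene = gene, points = pts, curve = curve,
                 first_exon = first_exon),
            class = "regional_profile")
}
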