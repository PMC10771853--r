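#' Read and write beta-value matrices
#'
#' Beta matrices are stored as TSV with the probe id in the first column
#' (header `probe_id`) and one column per sample. Values are validated into
#' \[0,1\] on read and written with 17 significant digits so that write/read
#' round-trips are lossless at double precision.
#'
#' @param path file path.
#' @return numeric matrix (probes x samples) with probe-id rownames.
#' @export
read_beta_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  .assert(ncol(dt) >= 2, "beta matrix file needs a probe id column plus samples")
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicated probe ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(dt)[-1])) {
    stop("duplicated sample ids in header", call. = FALSE)
  }
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  validate_beta_matrix(m)
  m
}

#' @rdname read_beta_matrix
#' @param beta numeric probes x samples matrix in \[0,1\].
#' @export
write_beta_matrix <- function(beta, path) {
  validate_beta_matrix(beta)
  dt <- data.table::as.data.table(
    apply(beta, 2, function(x) sprintf("%.17g", x)))
  dt <- cbind(data.table::data.table(probe_id = rownames(beta)), dt)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Validate a beta matrix
#'
#' Checks that the matrix has unique probe and sample ids, no missing values
#' and all values in \[0,1\]; errors name the offending probe and sample.
#' @param beta numeric matrix.
#' @export
validate_beta_matrix <- function(beta) {
  .assert(is.matrix(beta) && is.numeric(beta), "beta must be a numeric matrix")
  .assert(!is.null(rownames(beta)) && !is.null(colnames(beta)),
          "beta matrix needs probe rownames and sample colnames")
  .assert(!anyDuplicated(rownames(beta)), "duplicated probe ids")
  .assert(!anyDuplicated(colnames(beta)), "duplicated sample ids")
  if (anyNA(beta)) {
    idx <- which(is.na(beta), arr.ind = TRUE)[1, ]
    stop(sprintf("missing beta value at probe %s, sample %s",
                 rownames(beta)[idx[1]], colnames(beta)[idx[2]]),
         call. = FALSE)
  }
  bad <- which(beta < 0 | beta > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value out of [0,1] at probe %s, sample %s (%.4g)",
                 rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]],
                 beta[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read and write sample sheets (CSV)
#' @param path file path.
#' @export
read_sample_sheet <- function(path) {
  sh <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  .assert("sample_id" %in% names(sh), "sample sheet needs a sample_id column")
  .assert(!anyDuplicated(sh$sample_id), "duplicated sample ids in sheet")
  sh
}

#' @rdname read_sample_sheet
#' @param sheet sample-sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  data.table::fwrite(sheet, path, sep = ",", quote = FALSE)
  invisible(path)
}

#' Read and write probe manifests (TSV)
#'
#' Manifests carry probe id, chromosome label, 1-based position (hg19-style),
#' annotated gene (NA when absent) and gene feature; an `allosome` flag is
#' derived from the chromosome on read.
#' @param path file path.
#' @export
read_manifest <- function(path) {
  mf <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  .assert(all(c("probe_id", "chr", "pos") %in% names(mf)),
          "manifest needs columns probe_id, chr, pos")
  .assert(!anyDuplicated(mf$probe_id), "duplicated probe ids in manifest")
  .assert(all(mf$pos > 0), "manifest positions must be positive (1-based)")
  mf$allosome <- is_allosome(mf$chr)
  mf
}

#' @rdname read_manifest
#' @param manifest manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  keep <- intersect(c("probe_id", "chr", "pos", "gene", "feature"),
                    names(manifest))
  data.table::fwrite(manifest[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' @rdname read_manifest
#' @param chr chromosome labels (with or without "chr" prefix).
#' @export
is_allosome <- function(chr) {
  sub("^chr", "", chr) %in% c("X", "Y")
}

#' Read reference profiles (TSV: probe_id + 6 cell-type columns)
#' @param path file path.
#' @export
read_reference_profiles <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  .assert(identical(names(dt), c("probe_id", CELL_TYPES)),
          paste("reference file must have columns probe_id,",
                paste(CELL_TYPES, collapse = ", ")))
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- dt$probe_id
  .assert(all(m >= 0 & m <= 1), "reference betas must lie in [0,1]")
  m
}

#' @rdname read_reference_profiles
#' @param references probes x 6 matrix.
#' @export
write_reference_profiles <- function(references, path) {
  dt <- data.table::data.table(probe_id = rownames(references))
  for (ct in colnames(references)) dt[[ct]] <- sprintf("%.17g", references[, ct])
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Convert beta values to M-values
#'
#' M = log2((beta + offset) / (1 - beta + offset)). M-values are the
#' variance-stabilized scale used for statistical testing; betas are the
#' interpretable percentage-methylation scale used for reporting.
#'
#' @param beta values in \[0,1\] (vector or matrix).
#' @param offset small non-negative constant guarding against beta in {0,1};
#'   default 0, in which case boundary betas are rejected with an error
#'   advising an offset (e.g. 1e-6).
#' @return M-values, same shape as `beta`.
#' @export
beta_to_m <- function(beta, offset = 0) {
  .assert(offset >= 0, "offset must be non-negative")
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0,1]", call. = FALSE)
  }
  if (offset == 0 && any(beta == 0 | beta == 1, na.rm = TRUE)) {
    stop("beta values of exactly 0 or 1 give infinite M-values; ",
         "pass a small positive offset (e.g. 1e-6)", call. = FALSE)
  }
  log2((beta + offset) / (1 - beta + offset))
}

#' @rdname beta_to_m
#' @param m finite M-values.
#' @export
m_to_beta <- function(m) {
  .assert(all(is.finite(m)), "M-values must be finite")
  1 / (1 + 2^(-m))
}

#' Gap hunting: flag probes with multi-modal beta distributions
#'
#' SNPs under or near a probe produce bi- or tri-clustered beta distributions.
#' A probe is flagged when its sorted sample betas split, at gaps larger than
#' `threshold`, into two or more groups after discounting outlier groups
#' (groups holding less than `min_group_fraction` of samples).
#'
#' @param beta_row numeric vector of per-sample betas for one probe (>= 2).
#' @param threshold minimum gap between consecutive sorted values that starts
#'   a new group; default 0.3.
#' @param min_group_fraction groups smaller than this fraction of samples are
#'   treated as outliers and do not by themselves cause flagging; default 0.01.
#' @return list with `n_groups` (non-outlier groups), `group_sizes`,
#'   `boundaries` (value pairs flanking each gap), `largest_gap`, `flagged`.
#' @export
gap_hunt <- function(beta_row, threshold = 0.3, min_group_fraction = 0.01) {
  n <- length(beta_row)
  .assert(n >= 2, "gap hunting needs at least 2 samples")
  .assert(threshold > 0 && threshold < 1, "threshold must lie in (0,1)")
  s <- sort(beta_row)
  gaps <- diff(s)
  cut <- which(gaps > threshold)
  starts <- c(1L, cut + 1L)
  ends <- c(cut, n)
  sizes <- ends - starts + 1L
  outlier <- sizes / n < min_group_fraction
  n_groups <- sum(!outlier)
  list(
    n_groups = n_groups,
    group_sizes = sizes,
    boundaries = if (length(cut)) cbind(lower = s[cut], upper = s[cut + 1L])
                 else matrix(numeric(0), 0, 2,
                             dimnames = list(NULL, c("lower", "upper"))),
    largest_gap = if (length(gaps)) max(gaps) else 0,
    flagged = n_groups >= 2L
  )
}

#' @rdname gap_hunt
#' @param beta probes x samples beta matrix.
#' @return for the matrix variant, a data.frame with one row per probe:
#'   `probe_id`, `n_groups`, `largest_gap`, `flagged`.
#' @export
gap_hunt_matrix <- function(beta, threshold = 0.3, min_group_fraction = 0.01) {
  res <- apply(beta, 1, gap_hunt, threshold = threshold,
               min_group_fraction = min_group_fraction)
  data.frame(
    probe_id = rownames(beta),
    n_groups = vapply(res, `[[`, 1L, "n_groups"),
    largest_gap = vapply(res, `[[`, 1, "largest_gap"),
    flagged = vapply(res, `[[`, TRUE, "flagged"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Restrict a matrix to autosomal probes
#'
#' Probes hybridizing to the sex chromosomes are excluded from analysis to
#' avoid sex-driven methylation signal.
#'
#' @param mat probes x samples matrix.
#' @param manifest probe manifest covering all matrix probes (columns
#'   `probe_id`, `chr`).
#' @return the matrix restricted to autosomal probes, row order preserved.
#' @export
filter_allosomes <- function(mat, manifest) {
  missing <- setdiff(rownames(mat), manifest$probe_id)
  if (length(missing) > 0) {
    stop("probes missing from manifest: ",
         paste(head(missing, 10), collapse = ", "), call. = FALSE)
  }
  allo <- manifest$probe_id[is_allosome(manifest$chr)]
  keep <- !(rownames(mat) %in% allo)
  if (!any(keep)) warning("all probes are allosomal; returning empty matrix")
  mat[keep, , drop = FALSE]
}
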