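#' Declarative configuration for the end-to-end pipeline
#'
#' @param beta_path,sheet_path,manifest_path,references_path input files
#'   (TSV/CSV as written by the module writers); `references_path` and
#'   `gene_table_path` may be NULL when the corresponding stages are off.
#' @param gene_table_path optional TSV with columns gene, chr, start, end.
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages to run, in pipeline order, among
#'   `"preprocess"`, `"label"`, `"deconvolve"`, `"dm"`, `"genescan"`,
#'   `"classify"`. An empty vector is allowed and yields an empty run report.
#' @param covariates covariates for the adjusted differential-methylation
#'   design.
#' @param genes gene symbols for the gene-level scan.
#' @param gap_threshold,gap_min_group_fraction gap-hunting parameters.
#' @param m_offset offset used for the beta-to-M conversion.
#' @param drop_gap_flagged remove gap-flagged probes before analysis
#'   (default FALSE: flags are reported but probes retained).
#' @param boost a [boost_config()] for the classifier stage.
#' @param seed global seed, propagated to the classifier configuration.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(beta_path, sheet_path, manifest_path,
                            references_path = NULL, gene_table_path = NULL,
                            out_dir = "results",
                            stages = c("preprocess", "label", "deconvolve",
                                       "dm", "genescan", "classify"),
                            covariates = c("age", "sex", "smoking", "mtx"),
                            genes = NULL,
                            gap_threshold = 0.3,
                            gap_min_group_fraction = 0.01,
                            m_offset = 1e-6,
                            drop_gap_flagged = FALSE,
                            boost = NULL, seed = 1L) {
  all_stages <- c("preprocess", "label", "deconvolve", "dm", "genescan",
                  "classify")
  .assert(all(stages %in% all_stages),
          paste("unknown stages:",
                paste(setdiff(stages, all_stages), collapse = ", ")))
  if (is.null(boost)) boost <- boost_config(seed = seed)
  cfg <- list(beta_path = beta_path, sheet_path = sheet_path,
              manifest_path = manifest_path,
              references_path = references_path,
              gene_table_path = gene_table_path, out_dir = out_dir,
              stages = intersect(all_stages, stages),
              covariates = covariates, genes = genes,
              gap_threshold = gap_threshold,
              gap_min_group_fraction = gap_min_group_fraction,
              m_offset = m_offset, drop_gap_flagged = drop_gap_flagged,
              boost = boost, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate pipeline inputs without running anything
#'
#' Reads the configured input files and reports every violation found
#' (alignment between matrix, sheet and manifest; value ranges; duplicate
#' ids; label completeness) rather than stopping at the first.
#'
#' @param config a [pipeline_config()].
#' @return data.frame with columns `check` and `message`; zero rows when all
#'   inputs are consistent.
#' @export
validate_inputs <- function(config) {
  v <- list()
  add <- function(check, msg) v[[length(v) + 1]] <<- data.frame(
    check = check, message = msg, stringsAsFactors = FALSE)
  for (p in c(beta = config$beta_path, sheet = config$sheet_path,
              manifest = config$manifest_path)) {
    if (!file.exists(p)) add("path", paste("missing input file:", p))
  }
  if (length(v) > 0) return(do.call(rbind, v))

  beta <- tryCatch(read_beta_matrix(config$beta_path), error = function(e) e)
  if (inherits(beta, "error")) {
    add("beta", conditionMessage(beta)); beta <- NULL
  }
  sheet <- tryCatch(read_sample_sheet(config$sheet_path),
                    error = function(e) e)
  if (inherits(sheet, "error")) {
    add("sheet", conditionMessage(sheet)); sheet <- NULL
  }
  mf <- tryCatch(read_manifest(config$manifest_path), error = function(e) e)
  if (inherits(mf, "error")) {
    add("manifest", conditionMessage(mf)); mf <- NULL
  }
  if (!is.null(beta) && !is.null(sheet)) {
    extra <- setdiff(colnames(beta), sheet$sample_id)
    if (length(extra)) add("alignment",
      paste("samples in matrix but not in sheet:",
            paste(extra, collapse = ", ")))
    extra2 <- setdiff(sheet$sample_id, colnames(beta))
    if (length(extra2)) add("alignment",
      paste("samples in sheet but not in matrix:",
            paste(extra2, collapse = ", ")))
  }
  if (!is.null(beta) && !is.null(mf)) {
    miss <- setdiff(rownames(beta), mf$probe_id)
    if (length(miss)) add("alignment",
      paste("probes missing from manifest:",
            paste(head(miss, 10), collapse = ", ")))
  }
  if (!is.null(sheet)) {
    if (!"response" %in% names(sheet)) {
      if (!all(c("das28_baseline", "das28_followup") %in% names(sheet))) {
        add("labels", "sheet has neither response nor DAS28 columns")
      }
    } else if (anyNA(sheet$response)) {
      add("labels", paste("missing response labels for samples:",
        paste(sheet$sample_id[is.na(sheet$response)], collapse = ", ")))
    }
  }
  if (length(v) == 0) {
    data.frame(check = character(0), message = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, v)
  }
}

.stage_record <- function(name, rows_in, rows_out, elapsed, outputs) {
  list(stage = name, rows_in = rows_in, rows_out = rows_out,
       elapsed_s = round(elapsed, 3),
       outputs = lapply(outputs, function(f)
         list(path = f, md5 = unname(tools::md5sum(f)))))
}

#' Run the configured pipeline stages end to end
#'
#' Executes the enabled stages in fixed order (preprocess, label, deconvolve,
#' differential methylation, gene scan, classify) on shared intermediate
#' objects, writing each stage's artifacts under `out_dir` and recording a
#' machine-readable run report: per-stage input/output row counts, elapsed
#' times, output file checksums and the seed. The report is also written as
#' `run_report.json`. A failing stage halts the run with the stage named in
#' the error.
#'
#' @param config a [pipeline_config()].
#' @return the run report (list), invisibly also written to
#'   `out_dir/run_report.json`.
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "pipeline_config"), "need a pipeline_config()")
  viol <- validate_inputs(config)
  if (nrow(viol) > 0) {
    stop("input validation failed:\n",
         paste(sprintf("- [%s] %s", viol$check, viol$message),
               collapse = "\n"), call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages = list())
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    rec <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    rec$elapsed <- proc.time()[["elapsed"]] - t0
    report$stages[[name]] <<- .stage_record(name, rec$rows_in, rec$rows_out,
                                            rec$elapsed, rec$outputs)
  }

  beta <- read_beta_matrix(config$beta_path)
  sheet <- read_sample_sheet(config$sheet_path)
  manifest <- read_manifest(config$manifest_path)
  sheet <- sheet[match(colnames(beta), sheet$sample_id), , drop = FALSE]
  env <- new.env()
  env$beta <- beta

  run_stage("preprocess", function() {
    rows_in <- nrow(env$beta)
    b <- filter_allosomes(env$beta, manifest)
    gaps <- gap_hunt_matrix(b, config$gap_threshold,
                            config$gap_min_group_fraction)
    if (config$drop_gap_flagged) {
      b <- b[!gaps$flagged[match(rownames(b), gaps$probe_id)], ,
             drop = FALSE]
    }
    env$beta <- b
    env$m <- beta_to_m(b, offset = config$m_offset)
    f1 <- file.path(config$out_dir, "gap_report.tsv")
    data.table::fwrite(gaps, f1, sep = "\t")
    f2 <- file.path(config$out_dir, "m_values.tsv")
    dt <- data.table::data.table(probe_id = rownames(env$m))
    for (s in colnames(env$m)) dt[[s]] <- sprintf("%.17g", env$m[, s])
    data.table::fwrite(dt, f2, sep = "\t", quote = FALSE)
    list(rows_in = rows_in, rows_out = nrow(b), outputs = list(f1, f2))
  })

  run_stage("label", function() {
    if (!"response" %in% names(sheet)) {
      sheet$response <<- classify_das28(sheet$das28_baseline,
                                        sheet$das28_followup)
    }
    calls <- label_response(sheet$das28_baseline, sheet$das28_followup,
                            sheet$sample_id)
    f <- file.path(config$out_dir, "response_calls.csv")
    data.table::fwrite(calls, f, sep = ",")
    list(rows_in = nrow(sheet), rows_out = nrow(calls), outputs = list(f))
  })

  run_stage("deconvolve", function() {
    .assert(!is.null(config$references_path),
            "deconvolve stage needs references_path")
    refs <- read_reference_profiles(config$references_path)
    common <- intersect(rownames(refs), rownames(env$beta))
    .assert(length(common) > 0, "no deconvolution probes present in matrix")
    props <- estimate_proportions(env$beta[common, , drop = FALSE],
                                  refs[common, , drop = FALSE])
    cmp <- compare_proportions(props, sheet$response)
    f1 <- file.path(config$out_dir, "cell_proportions.csv")
    write_proportions(props, f1)
    f2 <- file.path(config$out_dir, "cell_anova.csv")
    data.table::fwrite(cmp$anova, f2, sep = ",")
    list(rows_in = length(common), rows_out = nrow(props$proportions),
         outputs = list(f1, f2))
  })

  run_stage("dm", function() {
    if (is.null(env$m)) env$m <- beta_to_m(env$beta, offset = config$m_offset)
    design <- build_design(sheet, config$covariates)
    env$dm <- fit_dm(env$m, design, env$beta)
    tab <- dm_table(env$dm, manifest)
    f <- file.path(config$out_dir, "differential_methylation.tsv")
    data.table::fwrite(tab, f, sep = "\t")
    list(rows_in = nrow(env$m), rows_out = nrow(tab), outputs = list(f))
  })

  run_stage("genescan", function() {
    .assert(!is.null(config$gene_table_path),
            "genescan stage needs gene_table_path")
    .assert(!is.null(env$dm), "genescan requires the dm stage")
    gt <- data.table::fread(config$gene_table_path, sep = "\t",
                            data.table = FALSE)
    ann <- annotate_probes(manifest, gt)
    genes <- if (is.null(config$genes)) unique(gt$gene) else config$genes
    scan <- gene_level_scan(env$dm, ann, env$m, genes)
    f <- file.path(config$out_dir, "gene_aggregates.tsv")
    data.table::fwrite(scan, f, sep = "\t")
    list(rows_in = nrow(env$dm), rows_out = nrow(scan), outputs = list(f))
  })

  run_stage("classify", function() {
    if (is.null(env$m)) env$m <- beta_to_m(env$beta, offset = config$m_offset)
    res <- stability_classify(t(env$m), sheet$response, config$boost)
    f1 <- file.path(config$out_dir, "panel.tsv")
    data.table::fwrite(res$panel, f1, sep = "\t")
    perf <- list(test_auroc = res$test_auroc,
                 mean_cv_auroc = res$mean_cv_auroc,
                 cv_auroc = res$stability$cv_auroc,
                 panel_size = sum(res$panel$in_panel),
                 seed = config$boost$seed)
    f2 <- file.path(config$out_dir, "classifier_performance.json")
    jsonlite::write_json(perf, f2, auto_unbox = TRUE, digits = NA,
                         na = "null")
    list(rows_in = nrow(env$m), rows_out = sum(res$panel$in_panel),
         outputs = list(f1, f2))
  })

  f <- file.path(config$out_dir, "run_report.json")
  jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA)
  report$path <- f
  invisible(report)
}

#' Verify that a run's output files are unchanged
#'
#' Recomputes the checksum of every output recorded in a run report and
#' errors on the first mismatch — guarding against tampered or regenerated
#' intermediates.
#'
#' @param report a run report from [run_pipeline()] or the path to its JSON.
#' @export
verify_run <- function(report) {
  if (is.character(report)) {
    report <- jsonlite::read_json(report, simplifyVector = FALSE)
  }
  for (st in report$stages) {
    for (out in st$outputs) {
      now <- unname(tools::md5sum(out$path))
      if (is.na(now) || !identical(now, out$md5)) {
        stop(sprintf("checksum mismatch for %s (stage %s)",
                     out$path, st$stage), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}
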