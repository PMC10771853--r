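#' Blood leukocyte types modelled by the synthetic generator and deconvolution
#'
#' The six major leukocyte populations resolvable from whole-blood methylation:
#' B cells, CD4+ T cells, CD8+ T cells, monocytes, neutrophils and NK cells.
#' @export
CELL_TYPES <- c("B", "CD4T", "CD8T", "Mono", "Neu", "NK")

# blood-realistic mean leukocyte fractions (neutrophil-dominant) used as the
# Dirichlet mean for synthetic mixtures
.CELL_MEANS <- c(B = 0.05, CD4T = 0.12, CD8T = 0.08, Mono = 0.08,
                 Neu = 0.60, NK = 0.07)

#' Configuration for the synthetic EPIC-like cohort generator
#'
#' Bundles and validates all knobs of [generate_cohort()]. Defaults describe a
#' desk-scale stand-in for a 92-patient rheumatoid-arthritis cohort starting
#' adalimumab: 49/92 responders, planted response effects whose beta-scale
#' magnitude (about 0.1 at mid-methylation) matches reported predictor-CpG
#' differences, tri-modal SNP-like probes, and covariate prevalences that
#' differ between responders and non-responders (smoking, concomitant
#' methotrexate).
#'
#' @param n_samples number of patients.
#' @param n_probes total number of CpG probes (including deconvolution probes
#'   supplied via the reference profiles).
#' @param n_celltypes number of leukocyte types; must be 6.
#' @param n_informative number of probes carrying a planted response effect.
#' @param delta_logit magnitude of the planted effect on the logit-methylation
#'   (M-value-like) scale; signs alternate across informative probes.
#' @param n_snp_probes number of SNP-affected probes with tri-modal betas.
#' @param noise_sd SD of logit-scale measurement noise (replicate-level
#'   technical noise of EPIC-style arrays; default 0.15).
#' @param covariate_effects named list; each element is `c(n_probes=, shift=)`
#'   planting a logit-scale shift driven by that binary covariate
#'   (`"smoking"`, `"mtx"` or `"sex"`).
#' @param covariate_assoc named list of per-group covariate distributions, see
#'   defaults; `age` is `c(mean_R, sd_R, mean_NR, sd_NR)`, binary covariates
#'   are `c(prev_R, prev_NR)`.
#' @param responder_fraction fraction of responders in (0,1).
#' @param das28 list with `baseline_mean`, `baseline_sd`, `followup_R`
#'   (mean, sd), `followup_NR` (mean, sd) on the 1-10 DAS28 scale.
#' @param dirichlet_concentration total concentration of the Dirichlet from
#'   which cell proportions are drawn.
#' @param seed integer seed; the whole cohort is a pure function of the config.
#' @return object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_samples = 92L,
                             n_probes = 2000L,
                             n_celltypes = 6L,
                             n_informative = 20L,
                             delta_logit = 0.4,
                             n_snp_probes = 20L,
                             noise_sd = 0.15,
                             covariate_effects = list(),
                             covariate_assoc = list(
                               female  = c(0.796, 0.744),
                               smoking = c(0.204, 0.429),
                               mtx     = c(0.857, 0.651),
                               age     = c(52.7, 9.3, 55.4, 12.5)
                             ),
                             responder_fraction = 49 / 92,
                             das28 = list(baseline_mean = 4.8, baseline_sd = 1.2,
                                          followup_R = c(2.6, 1.2),
                                          followup_NR = c(3.8, 1.4)),
                             dirichlet_concentration = 50,
                             seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_probes = as.integer(n_probes),
    n_celltypes = as.integer(n_celltypes),
    n_informative = as.integer(n_informative), delta_logit = delta_logit,
    n_snp_probes = as.integer(n_snp_probes), noise_sd = noise_sd,
    covariate_effects = covariate_effects, covariate_assoc = covariate_assoc,
    responder_fraction = responder_fraction, das28 = das28,
    dirichlet_concentration = dirichlet_concentration, seed = as.integer(seed)
  )
  .assert(cfg$n_samples >= 4, "n_samples must be at least 4")
  .assert(cfg$n_celltypes == 6L, "exactly 6 cell types are supported")
  .assert(cfg$n_informative + cfg$n_snp_probes <= cfg$n_probes,
          "n_informative + n_snp_probes must not exceed n_probes")
  .assert(cfg$responder_fraction > 0 && cfg$responder_fraction < 1,
          "responder_fraction must lie in (0,1)")
  .assert(cfg$noise_sd >= 0, "noise_sd must be non-negative")
  bad <- setdiff(names(cfg$covariate_effects), c("smoking", "mtx", "sex"))
  .assert(length(bad) == 0,
          paste0("unsupported covariate_effects entries: ",
                 paste(bad, collapse = ", ")))
  class(cfg) <- "generator_config"
  cfg
}

#' Synthetic sorted-cell reference methylation profiles
#'
#' Builds mean beta profiles for the six leukocyte types over a deconvolution
#' probe set. Each type gets `n_discriminating_per_type` probes that are
#' highly methylated (beta near 0.9) in that type and lowly methylated
#' (near 0.1) in all others; remaining probes share a common baseline across
#' types. This mirrors how discriminating probe panels for reference-based
#' blood deconvolution are constructed, without claiming any real profile.
#'
#' @param n_probes number of reference probes (>= 6 * n_discriminating_per_type).
#' @param n_discriminating_per_type discriminating probes per cell type.
#' @param seed integer seed.
#' @return probes x 6 numeric matrix in \[0,1\] with probe-id rownames and
#'   cell-type colnames.
#' @export
generate_reference_profiles <- function(n_probes, n_discriminating_per_type,
                                        seed = 1L) {
  n_probes <- as.integer(n_probes)
  k <- as.integer(n_discriminating_per_type)
  if (n_probes < 6L * k) {
    stop(sprintf("n_probes (%d) must be at least 6 * n_discriminating_per_type (%d)",
                 n_probes, 6L * k), call. = FALSE)
  }
  set.seed(seed)
  R <- matrix(NA_real_, n_probes, 6L,
              dimnames = list(sprintf("decon_%04d", seq_len(n_probes)),
                              CELL_TYPES))
  for (j in seq_len(6L)) {
    rows <- ((j - 1L) * k + 1L):(j * k)
    block <- matrix(0.1 + runif(k * 6L, -0.02, 0.02), k, 6L)
    block[, j] <- 0.9 + runif(k, -0.02, 0.02)
    R[rows, ] <- block
  }
  if (n_probes > 6L * k) {
    base <- runif(n_probes - 6L * k, 0.2, 0.8)
    R[(6L * k + 1L):n_probes, ] <- matrix(rep(base, 6L), ncol = 6L)
  }
  R
}

# Dirichlet draws via independent gammas
.rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

# draw a DAS28 follow-up consistent with the intended label; redraw on
# indeterminate/conflict draws, with a deterministic fallback so labels are
# always unambiguous
.draw_followup <- function(baseline, intended, mu, sdv, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    fu <- .clamp(rnorm(1, mu, sdv), 0, 10)
    if (classify_das28(baseline, fu) == intended) return(fu)
  }
  if (intended == "responder") {
    min(3.0, baseline - 1.3)
  } else {
    max(.clamp(baseline + 0.2, 0, 10), 3.3)
  }
}

#' Generate a seeded synthetic methylation cohort with known ground truth
#'
#' Emulates a whole-blood EPIC-style cohort of rheumatoid-arthritis patients
#' assessed for therapy response: per-sample leukocyte mixtures drawn from a
#' Dirichlet and combined with reference profiles on the deconvolution probes,
#' response-associated effects planted on the logit-methylation scale,
#' tri-modal SNP-like probes with Hardy-Weinberg genotype frequencies,
#' optional covariate-driven shifts, logit-normal measurement noise, and
#' DAS28 baseline/follow-up scores drawn so the response rule reproduces the
#' intended label for every sample.
#'
#' @param config a [generator_config()].
#' @param references reference profile matrix from
#'   [generate_reference_profiles()]; its probes become the cohort's
#'   deconvolution probe set.
#' @return list with elements `beta` (probes x samples matrix), `sheet`
#'   (sample-sheet data.frame), `manifest` (probe manifest data.frame) and
#'   `truth` (ground-truth record: informative probe deltas, SNP probe
#'   cluster means, true cell proportions, responder ids, seed).
#' @export
generate_cohort <- function(config, references) {
  .assert(inherits(config, "generator_config"),
          "config must be created by generator_config()")
  .assert(is.matrix(references) && ncol(references) == 6L,
          "references must be a probes x 6 matrix")
  n_dec <- nrow(references)
  n <- config$n_samples
  n_cov_probes <- sum(vapply(config$covariate_effects,
                             function(e) as.integer(e[["n_probes"]]), 1L))
  .assert(n_dec + config$n_informative + config$n_snp_probes + n_cov_probes
          <= config$n_probes,
          "n_probes too small for deconvolution + planted + covariate probes")

  set.seed(config$seed)
  sample_ids <- sprintf("S%03d", seq_len(n))
  n_resp <- as.integer(round(config$responder_fraction * n))
  resp_idx <- sort(sample.int(n, n_resp))
  is_resp <- seq_len(n) %in% resp_idx
  response <- ifelse(is_resp, "responder", "non_responder")

  # clinical covariates with group-specific distributions
  ca <- config$covariate_assoc
  prev <- function(v) ifelse(is_resp, v[1], v[2])
  female  <- rbinom(n, 1, prev(ca$female))
  smoking <- rbinom(n, 1, prev(ca$smoking))
  mtx     <- rbinom(n, 1, prev(ca$mtx))
  age <- ifelse(is_resp, rnorm(n, ca$age[1], ca$age[2]),
                rnorm(n, ca$age[3], ca$age[4]))
  age <- round(.clamp(age, 18, 90), 1)

  # DAS28 trajectories consistent with the intended label
  das_base <- .clamp(rnorm(n, config$das28$baseline_mean,
                           config$das28$baseline_sd), 0, 10)
  das_fu <- numeric(n)
  for (i in seq_len(n)) {
    pars <- if (is_resp[i]) config$das28$followup_R else config$das28$followup_NR
    das_fu[i] <- .draw_followup(das_base[i], response[i], pars[1], pars[2])
  }

  # probe layout: deconvolution probes first, then informative, SNP,
  # covariate-affected, background
  n_extra <- config$n_probes - n_dec
  extra_ids <- sprintf("cg%08d", seq_len(n_extra))
  probe_ids <- c(rownames(references), extra_ids)
  ofs <- n_dec
  inf_ids <- extra_ids[seq_len(config$n_informative)]
  snp_ids <- extra_ids[config$n_informative + seq_len(config$n_snp_probes)]
  used <- config$n_informative + config$n_snp_probes
  cov_probe_ids <- list()
  for (nm in names(config$covariate_effects)) {
    np <- as.integer(config$covariate_effects[[nm]][["n_probes"]])
    cov_probe_ids[[nm]] <- extra_ids[used + seq_len(np)]
    used <- used + np
  }

  # true cell proportions and mixture means on deconvolution probes
  alpha <- config$dirichlet_concentration * .CELL_MEANS
  W <- .rdirichlet(n, alpha)
  dimnames(W) <- list(sample_ids, CELL_TYPES)
  mu <- matrix(NA_real_, config$n_probes, n,
               dimnames = list(probe_ids, sample_ids))
  mu[seq_len(n_dec), ] <- references %*% t(W)

  # background baseline betas (shared across samples per probe)
  baseline <- runif(n_extra, 0.1, 0.9)
  if (n_extra > 0) {
    mu[n_dec + seq_len(n_extra), ] <- matrix(rep(baseline, n), ncol = n)
  }

  # planted response effects: alternating-sign logit shifts in responders
  inf_delta <- numeric(0)
  if (config$n_informative > 0) {
    inf_delta <- config$delta_logit *
      rep_len(c(1, -1), config$n_informative)
    names(inf_delta) <- inf_ids
    shift <- outer(inf_delta, as.numeric(is_resp))
    mu[inf_ids, ] <- .invlogit(.logit(mu[inf_ids, , drop = FALSE]) + shift)
  }

  # SNP-like probes: Hardy-Weinberg genotypes at allele frequency 0.5,
  # cluster means beta = 0.05 / 0.50 / 0.95
  snp_clusters <- c(0.05, 0.50, 0.95)
  if (config$n_snp_probes > 0) {
    geno <- matrix(sample(0:2, config$n_snp_probes * n, replace = TRUE,
                          prob = c(0.25, 0.5, 0.25)),
                   config$n_snp_probes, n)
    mu[snp_ids, ] <- matrix(snp_clusters[geno + 1L], config$n_snp_probes, n)
  }

  # covariate-driven logit shifts
  cov_values <- list(smoking = smoking, mtx = mtx, sex = female)
  for (nm in names(config$covariate_effects)) {
    sh <- config$covariate_effects[[nm]][["shift"]]
    ids <- cov_probe_ids[[nm]]
    shift <- outer(rep(sh, length(ids)), as.numeric(cov_values[[nm]]))
    mu[ids, ] <- .invlogit(.logit(mu[ids, , drop = FALSE]) + shift)
  }

  # logit-normal measurement noise; the zero-noise limit returns mixtures
  # exactly so noiseless identities hold bitwise
  if (config$noise_sd > 0) {
    eps <- 1e-6
    lg <- .logit(.clamp(mu, eps, 1 - eps))
    beta <- .invlogit(lg + matrix(rnorm(length(mu), 0, config$noise_sd),
                                  nrow(mu), ncol(mu)))
  } else {
    beta <- mu
  }

  manifest <- data.frame(
    probe_id = probe_ids,
    chr = paste0("chr", (seq_along(probe_ids) - 1L) %% 22L + 1L),
    pos = 10000L + 1000L * ((seq_along(probe_ids) - 1L) %/% 22L),
    gene = NA_character_,
    feature = "unknown",
    stringsAsFactors = FALSE
  )

  sheet <- data.frame(
    sample_id = sample_ids,
    das28_baseline = round(das_base, 2),
    das28_followup = round(das_fu, 2),
    age = age, sex = ifelse(female == 1, "F", "M"),
    smoking = smoking, mtx = mtx,
    response = response,
    stringsAsFactors = FALSE
  )
  # labels must survive the rounding of the emitted DAS28 columns
  relab <- classify_das28(sheet$das28_baseline, sheet$das28_followup)
  fix <- which(relab != response)
  for (i in fix) {
    if (response[i] == "responder") {
      sheet$das28_followup[i] <- min(3.0, sheet$das28_baseline[i] - 1.3)
    } else {
      sheet$das28_followup[i] <-
        max(.clamp(sheet$das28_baseline[i] + 0.2, 0, 10), 3.3)
    }
  }

  truth <- list(
    informative_probe_ids = inf_ids,
    informative_delta_logit = as.list(inf_delta),
    snp_probe_ids = snp_ids,
    snp_cluster_means = snp_clusters,
    covariate_probe_ids = cov_probe_ids,
    deconvolution_probe_ids = rownames(references),
    true_cell_proportions = W,
    responder_ids = sample_ids[resp_idx],
    seed = config$seed
  )
  list(beta = beta, sheet = sheet, manifest = manifest, truth = truth)
}

#' Write every cohort artifact to a directory
#'
#' Writes the beta matrix (TSV), sample sheet (CSV), probe manifest (TSV) and
#' ground-truth record (JSON); all round-trip losslessly through the package
#' readers.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir target directory, created if needed.
#' @param references optional reference profiles to write alongside.
#' @return named list of the written file paths.
#' @export
write_cohort <- function(cohort, dir, references = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    beta = file.path(dir, "beta_matrix.tsv"),
    sheet = file.path(dir, "sample_sheet.csv"),
    manifest = file.path(dir, "manifest.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_beta_matrix(cohort$beta, paths$beta)
  write_sample_sheet(cohort$sheet, paths$sheet)
  write_manifest(cohort$manifest, paths$manifest)
  write_truth(cohort$truth, paths$truth)
  if (!is.null(references)) {
    paths$references <- file.path(dir, "reference_profiles.tsv")
    write_reference_profiles(references, paths$references)
  }
  paths
}

#' Write a ground-truth record as JSON
#'
#' @param truth the `truth` element of [generate_cohort()] output.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  tr <- truth
  W <- tr$true_cell_proportions
  Wd <- data.frame(sample_id = rownames(W), as.data.frame(W))
  rownames(Wd) <- NULL          # keep write_json from adding a "_row" field
  tr$true_cell_proportions <- Wd
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  Wd <- as.data.frame(tr$true_cell_proportions)
  W <- as.matrix(Wd[, intersect(names(Wd), CELL_TYPES), drop = FALSE])
  storage.mode(W) <- "double"
  rownames(W) <- Wd$sample_id
  tr$true_cell_proportions <- W
  tr
}
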