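fisher_p <- function(p) {
  pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

test_that("Brown's method reduces to Fisher under independence", {
  set.seed(101)
  for (k in 1:10) {
    p <- runif(k, 1e-6, 1)
    bc <- brown_combine(p)
    expect_equal(bc$psi, -2 * sum(log(p)), tolerance = 1e-12)
    expect_equal(bc$p_value, fisher_p(p), tolerance = 1e-12)
    expect_equal(bc$df, 2 * k)
    expect_equal(bc$scale, 1)
  }
  # worked example, frozen against the independent oracle
  bc <- brown_combine(c(0.01, 0.5, 0.9))
  expect_equal(bc$psi, 10.8073557644117, tolerance = 1e-10)
  expect_equal(bc$p_value, 0.0945159534428683, tolerance = 1e-10)
})

test_that("Brown's method has the right single-test and perfect-correlation limits", {
  # k = 1: the combined p-value is the input p-value
  for (p in c(0.001, 0.25, 0.8, 1)) {
    expect_equal(brown_combine(p)$p_value, p, tolerance = 1e-12)
  }
  # all correlations 1 with identical p-values: k copies of one test carry
  # no extra evidence, the combined p is the input p
  for (k in 2:6) {
    R <- matrix(1, k, k)
    for (p0 in c(0.01, 0.2, 0.7)) {
      bc <- brown_combine(rep(p0, k), R)
      expect_equal(bc$p_value, p0, tolerance = 1e-10)
      expect_equal(bc$df, 2, tolerance = 1e-12)
    }
  }
})

test_that("combined p is monotone in the inputs and df shrinks with correlation", {
  base <- c(0.05, 0.3, 0.6)
  grid <- seq(0.01, 0.99, by = 0.07)
  ps <- vapply(grid, function(g)
    brown_combine(c(g, base[2], base[3]))$p_value, 0)
  expect_true(all(diff(ps) > 0))
  # effective df decreases as the common correlation rises
  rhos <- seq(0, 0.9, by = 0.1)
  dfs <- vapply(rhos, function(r) {
    R <- matrix(r, 3, 3); diag(R) <- 1
    brown_combine(base, R)$df
  }, 0)
  expect_true(all(diff(dfs) < 0))
  # and the combined p-value under correlation is never smaller than the
  # Fisher p for this evidence pattern (correlation discounts evidence)
  expect_true(all(vapply(rhos[-1], function(r) {
    R <- matrix(r, 3, 3); diag(R) <- 1
    brown_combine(base, R)$p_value
  }, 0) > brown_combine(base)$p_value))
})

test_that("brown_combine validates its inputs", {
  expect_error(brown_combine(c(0, 0.5)), "floor")
  expect_error(brown_combine(c(0.5, 1.2)), "\\(0,1\\]")
  R <- matrix(c(1, 0.5, 0.2, 1), 2, 2)
  expect_error(brown_combine(c(0.1, 0.2), R), "symmetric")
  R2 <- matrix(c(2, 0, 0, 2), 2, 2)
  expect_error(brown_combine(c(0.1, 0.2), R2), "unit diagonal")
  R3 <- matrix(c(1, -0.9, -0.9, -0.9, 1, -0.9, -0.9, -0.9, 1), 3, 3)
  expect_warning(brown_combine(c(0.1, 0.2, 0.3), R3), "positive semi-definite")
})

test_that("probes annotate to the nearest gene with a hard 20 kb cutoff", {
  genes <- data.frame(
    gene = c("ALPHA", "BETA", "GAMMA"),
    chr = c("chr1", "chr1", "chr2"),
    start = c(50000, 120000, 1000),
    end = c(60000, 130000, 2000),
    stringsAsFactors = FALSE
  )
  mf <- data.frame(
    probe_id = sprintf("cg%02d", 1:7),
    chr = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2", "chr3"),
    pos = c(55000,   # inside ALPHA body -> distance 0
            30000,   # 20000 upstream of ALPHA -> inclusive boundary
            29999,   # 20001 upstream -> out of range
            90000,   # between the genes, 30000 from both -> unannotated
            100500,  # 19500 from BETA, 40500 from ALPHA -> BETA
            2100,    # 100 downstream of GAMMA
            500),    # chromosome with no genes
    stringsAsFactors = FALSE
  )
  ann <- annotate_probes(mf, genes)
  expect_identical(ann$gene,
                   c("ALPHA", "ALPHA", NA, NA, "BETA", "GAMMA", NA))
  expect_equal(ann$gene_distance, c(0, 20000, NA, NA, 19500, 100, NA))
})

test_that("annotation ties break by midpoint distance then symbol", {
  # probe inside two overlapping genes (both distance 0): nearer midpoint wins
  genes <- data.frame(gene = c("WIDE", "NARROW"), chr = "chr1",
                      start = c(1000, 4000), end = c(9000, 6000),
                      stringsAsFactors = FALSE)
  mf <- data.frame(probe_id = "cg01", chr = "chr1", pos = 4800,
                   stringsAsFactors = FALSE)
  # midpoints: WIDE 5000 (dist 200), NARROW 5000 (dist 200) -> symbol tie,
  # NARROW < WIDE lexicographically
  expect_identical(annotate_probes(mf, genes)$gene, "NARROW")
  # shift the probe so WIDE's midpoint is closer
  mf$pos <- 5200
  genes$start[2] <- 4500; genes$end[2] <- 6500   # NARROW midpoint 5500
  expect_identical(annotate_probes(mf, genes)$gene, "WIDE")
  expect_error(annotate_probes(mf, data.frame(gene = "X", chr = "chr1",
                                              start = 10, end = 5)),
               "malformed")
})

test_that("gene aggregation is calibrated where naive Fisher is not", {
  # 5 equicorrelated probes (rho = 0.6) per replicate gene, no true effect:
  # Brown keeps the type-I rate near alpha, Fisher on the same p-values is
  # anti-conservative
  set.seed(111)
  k <- 5; n <- 80; rho <- 0.6; nrep <- 2000
  Sig <- matrix(rho, k, k); diag(Sig) <- 1
  L <- chol(Sig)
  sheet <- data.frame(sample_id = sprintf("S%03d", 1:n),
                      response = rep(c("responder", "non_responder"),
                                     each = n / 2),
                      stringsAsFactors = FALSE)
  X <- build_design(sheet)
  ann <- data.frame(probe_id = sprintf("cg%02d", 1:k), chr = "chr1",
                    pos = 1:k * 100, gene = "G", stringsAsFactors = FALSE)
  p_brown <- p_fisher <- numeric(nrep)
  for (i in seq_len(nrep)) {
    m <- t(matrix(rnorm(n * k), n, k) %*% L)
    rownames(m) <- ann$probe_id; colnames(m) <- sheet$sample_id
    dm <- fit_dm(m, X)
    sc <- gene_level_scan(dm, ann, m, "G")
    p_brown[i] <- sc$p_value
    p_fisher[i] <- fisher_p(dm$p_value)
  }
  t1_brown <- mean(p_brown < 0.05)
  t1_fisher <- mean(p_fisher < 0.05)
  expect_gte(t1_brown, 0.03)
  expect_lte(t1_brown, 0.07)
  expect_gt(t1_fisher, 0.08)
})

test_that("gene aggregation detects a shared planted effect", {
  set.seed(112)
  k <- 5; n <- 80; rho <- 0.4
  Sig <- matrix(rho, k, k); diag(Sig) <- 1
  L <- chol(Sig)
  sheet <- data.frame(sample_id = sprintf("S%03d", 1:n),
                      response = rep(c("responder", "non_responder"),
                                     each = n / 2),
                      stringsAsFactors = FALSE)
  X <- build_design(sheet)
  ann <- data.frame(probe_id = sprintf("cg%02d", 1:k), chr = "chr1",
                    pos = 1:k * 100, gene = "G", stringsAsFactors = FALSE)
  hits <- 0
  for (i in 1:50) {
    m <- t(matrix(rnorm(n * k), n, k) %*% L)
    m[, sheet$response == "responder"] <-
      m[, sheet$response == "responder"] + 0.8
    rownames(m) <- ann$probe_id; colnames(m) <- sheet$sample_id
    sc <- gene_level_scan(fit_dm(m, X), ann, m, "G")
    if (sc$p_value < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("gene_level_scan reports absent genes and single-probe genes", {
  sheet <- data.frame(sample_id = sprintf("S%02d", 1:20),
                      response = rep(c("responder", "non_responder"), 10),
                      stringsAsFactors = FALSE)
  X <- build_design(sheet)
  set.seed(113)
  m <- matrix(rnorm(3 * 20), 3, 20,
              dimnames = list(c("cg01", "cg02", "cg03"), sheet$sample_id))
  ann <- data.frame(probe_id = rownames(m), chr = "chr1", pos = 1:3 * 100,
                    gene = c("A", "A", "B"), stringsAsFactors = FALSE)
  dm <- fit_dm(m, X)
  sc <- gene_level_scan(dm, ann, m, c("A", "B", "MISSING"))
  expect_equal(sc$n_probes, c(2L, 1L, 0L))
  expect_true(is.na(sc$p_value[3]))
  # a single-probe gene passes its p-value through unchanged
  expect_equal(sc$p_value[2], dm$p_value[3], tolerance = 1e-12)
})

test_that("regional profiles smooth ordered points and handle sparse genes", {
  ann <- data.frame(probe_id = sprintf("cg%02d", 1:12), chr = "chr1",
                    pos = c(seq(1000, 10000, length.out = 11), 500),
                    gene = c(rep("G", 11), "G"), stringsAsFactors = FALSE)
  # a linear delta-methylation trend along the region
  dm <- data.frame(probe_id = ann$probe_id,
                   delta_meth = 0.00001 * ann$pos,
                   stringsAsFactors = FALSE)
  rp <- regional_profile("G", dm, ann, span = 1)
  expect_s3_class(data.frame(rp$points), "data.frame")
  expect_true(!is.unsorted(rp$points$pos))
  expect_equal(nrow(rp$curve), 200)
  # degree-1 loess with full span reproduces a linear trend
  expect_equal(rp$curve$fit, 0.00001 * rp$curve$pos, tolerance = 1e-6)
  expect_true(all(rp$curve$se >= 0))
  # constant profile -> flat fitted curve
  dm2 <- dm; dm2$delta_meth <- 0.07
  rp2 <- regional_profile("G", dm2, ann)
  expect_equal(rp2$curve$fit, rep(0.07, 200), tolerance = 1e-8)
  # fewer than 3 probes: points only, with a notice
  ann3 <- ann[1:2, ]
  expect_message(rp3 <- regional_profile("G", dm, ann3), "fewer than 3")
  expect_null(rp3$curve)
  expect_equal(nrow(rp3$points), 2)
  expect_error(regional_profile("G", dm, ann, span = 0), "span")
})
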