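test_that("spearman coexpression matches the rank-then-Pearson oracle", {
  expect_equal(spearman_coexpression(1:6, c(2, 5, 7, 8, 11, 20)), 1)
  expect_equal(spearman_coexpression(1:6, rev(1:6)), -1)
  set.seed(42)
  for (i in 1:20) {
    x <- sample(1:4, 6, replace = TRUE)  # ties guaranteed
    y <- rnorm(6)
    expect_equal(spearman_coexpression(x, y), spearman_oracle(x, y))
  }
  # fewer than 3 shared non-missing conditions: undefined
  expect_true(is.na(spearman_coexpression(c(1, 2, NA, NA), c(1, NA, 2, 3))))
  # named profiles match on shared condition names
  a <- c(c1 = 1, c2 = 2, c3 = 3, c4 = 4)
  b <- c(c2 = 5, c3 = 6, c4 = 9, c9 = 0)
  expect_equal(spearman_coexpression(a, b), 1)
})

test_that("spearman coexpression is symmetric and monotone-invariant", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(spearman_coexpression(x, y), spearman_coexpression(y, x))
    expect_equal(spearman_coexpression(exp(2 * x) + 5, y),
                 spearman_coexpression(x, y))
  }
})

test_that("Mann-Whitney comparison matches brute-force pair counting", {
  res <- compare_groups(c(3, 4), c(1, 2))
  expect_equal(res$U, 4)                      # complete separation
  expect_equal(compare_groups(c(1, 2), c(3, 4))$U, 0)
  # identical lists: exact enumeration gives P = 1
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p_value, 1,
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:10) {
    a <- sample(1:5, 6, replace = TRUE)
    b <- sample(1:5, 6, replace = TRUE)
    expect_equal(compare_groups(a, b)$U, u_oracle(a, b))
    # exchanging groups leaves the two-sided P unchanged
    expect_equal(compare_groups(a, b)$p_value, compare_groups(b, a)$p_value)
  }
  # approximation branch keeps the brute-force U
  a <- rnorm(20); b <- rnorm(15)
  expect_equal(compare_groups(a, b)$U, u_oracle(a, b))
  expect_error(compare_groups(numeric(0), 1), "non-empty")
})

test_that("bootstrap median CI is deterministic with known edge cases", {
  expect_equal(unname(bootstrap_median_ci(rep(2.5, 10), seed = 1)),
               c(2.5, 2.5))
  v <- rnorm(40)
  expect_identical(bootstrap_median_ci(v, seed = 99),
                   bootstrap_median_ci(v, seed = 99))
  expect_error(bootstrap_median_ci(1, seed = 1), "at least 2")
})

test_that("bootstrap median CI has near-nominal coverage", {
  set.seed(31)
  hits <- vapply(1:500, function(i) {
    v <- rnorm(200)
    ci <- bootstrap_median_ci(v, n_boot = 400L, seed = i)
    ci[[1L]] <= 0 && 0 <= ci[[2L]]
  }, logical(1L))
  expect_gte(mean(hits), 0.92)
  expect_lte(mean(hits), 0.98)
})

test_that("coexpression background enumerates small genomes and samples large ones", {
  vals <- matrix(rnorm(4 * 10), 4, 10,
                 dimnames = list(sprintf("g%d", 1:4), sprintf("c%d", 1:10)))
  em <- expression_matrix(vals, "sp")
  rho <- coexpression_background(em, n_pairs = 3, seed = 1)
  expect_length(rho, choose(4, 2))

  big <- matrix(rnorm(2100 * 20), 2100, 20,
                dimnames = list(sprintf("g%04d", 1:2100),
                                sprintf("c%d", 1:20)))
  emb <- expression_matrix(big, "sp")
  r1 <- coexpression_background(emb, n_pairs = 5000, seed = 2)
  r2 <- coexpression_background(emb, n_pairs = 5000, seed = 2)
  expect_identical(r1, r2)
  expect_length(r1, 5000L)
  # independent profiles: mean rho near zero
  expect_lt(abs(mean(r1)), 0.02)
})

test_that("expression divergence recovers planted divergence ranking", {
  set.seed(17)
  n_genes <- 500L; n_cond <- 30L
  genes <- sprintf("g%03d", seq_len(n_genes))
  conds <- as.vector(rbind(sprintf("c%02d.r1", 1:n_cond),
                           sprintf("c%02d.r2", 1:n_cond)))
  d_true <- runif(n_genes, 0.05, 0.9)
  z <- matrix(rnorm(n_genes * n_cond), n_genes)
  w <- matrix(rnorm(n_genes * n_cond), n_genes)
  mk <- function(latent, id, prefix = NULL) {
    vals <- matrix(NA_real_, n_genes, 2L * n_cond,
                   dimnames = list(if (is.null(prefix)) genes else
                     paste0(prefix, genes), conds))
    for (j in seq_len(n_cond)) {
      for (r in 1:2) {
        vals[, 2L * (j - 1L) + r] <- latent[, j] + rnorm(n_genes, sd = 0.1)
      }
    }
    expression_matrix(vals, id, infer_replicate_groups(conds))
  }
  m_focal <- mk(z, "sp00")
  m_other <- mk(sqrt(1 - d_true) * z + sqrt(d_true) * w, "s1",
                prefix = "s1_")
  om <- make_orthomap(list(s1 = genes))
  prof <- expression_divergence(list(sp00 = m_focal, s1 = m_other), om,
                                "sp00")
  expect_gt(cor(prof$divergence[genes], d_true, method = "spearman"), 0.9)
  # normalization invariant: each component has mean 0, sd 1 over genes
  comp <- prof$pairwise_components[[1L]]
  expect_equal(mean(comp, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_equal(sd(comp, na.rm = TRUE), 1, tolerance = 1e-9)
  # intraspecies baseline reflects the replicate noise level
  expect_true(all(prof$intraspecies_baseline > 0))
})

test_that("degenerate divergence input is rejected", {
  genes <- sprintf("g%d", 1:5)
  conds <- as.vector(rbind(sprintf("c%d.r1", 1:4), sprintf("c%d.r2", 1:4)))
  vals <- matrix(rep(seq_len(8), each = 5), 5, 8,
                 dimnames = list(genes, conds))
  m1 <- expression_matrix(vals, "sp00", infer_replicate_groups(conds))
  m2 <- expression_matrix(
    `rownames<-`(vals, paste0("s1_", genes)), "s1",
    infer_replicate_groups(conds))
  om <- make_orthomap(list(s1 = genes))
  expect_error(expression_divergence(list(sp00 = m1, s1 = m2), om, "sp00"),
               "degenerate|zero variance")
})

test_that("dropping a species pair only changes genes represented in it", {
  set.seed(23)
  genes <- sprintf("g%03d", 1:80)
  conds <- as.vector(rbind(sprintf("c%02d.r1", 1:12),
                           sprintf("c%02d.r2", 1:12)))
  mk <- function(id, gene_ids) {
    vals <- matrix(rnorm(length(gene_ids) * length(conds)),
                   length(gene_ids), length(conds),
                   dimnames = list(gene_ids, conds))
    expression_matrix(vals, id, infer_replicate_groups(conds))
  }
  # genes g001..g040 have orthologs in s2; the rest only in s1
  present <- list(s1 = genes, s2 = genes[1:40])
  om <- make_orthomap(present)
  mats <- list(sp00 = mk("sp00", genes),
               s1 = mk("s1", paste0("s1_", genes)),
               s2 = mk("s2", paste0("s2_", genes[1:40])))
  full <- expression_divergence(mats, om, "sp00")
  reduced <- expression_divergence(mats[c("sp00", "s1")], om, "sp00")
  unaffected <- genes[41:80]
  # genes without s2 orthologs keep the identical (sp00, s1) component
  expect_equal(full$pairwise_components[["sp00|s1"]][unaffected],
               reduced$pairwise_components[["sp00|s1"]][unaffected])
})

test_that("planted coexpressed cross pairs beat null pairs in group contrast", {
  set.seed(61)
  n_pairs <- 200L; n_cond <- 50L; rho <- 0.4
  planted <- vapply(seq_len(n_pairs), function(i) {
    f <- rnorm(n_cond)
    x <- sqrt(rho) * f + sqrt(1 - rho) * rnorm(n_cond)
    y <- sqrt(rho) * f + sqrt(1 - rho) * rnorm(n_cond)
    spearman_coexpression(x, y)
  }, numeric(1L))
  null_rho <- vapply(seq_len(n_pairs), function(i) {
    spearman_coexpression(rnorm(n_cond), rnorm(n_cond))
  }, numeric(1L))
  res <- compare_groups(planted, null_rho)
  expect_lt(res$p_value, 0.01)
  expect_gt(median(planted), median(null_rho))
})
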