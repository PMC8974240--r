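# Kinship, PCA, panel subsetting, allele stats, and the MLM scan.

test_that("kinship matches an elementwise hand computation on a 4x3 toy", {
  M <- matrix(c(0, 2, 0,
                2, 0, 0,
                0, 2, 2,
                2, 0, 2), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("a", 1:4), paste0("s", 1:3)))
  K <- centered_kinship(M)
  C <- scale(M, center = TRUE, scale = FALSE)
  s <- sum(colSums(C^2) / 4)
  expect_equal(K$K, tcrossprod(C) / s, tolerance = 1e-12)
  expect_lt(max(abs(rowSums(K$K))), 1e-10)
  expect_equal(K$K, t(K$K))
  ev <- eigen(K$K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("duplicate accessions have identical kinship rows", {
  G <- small_panel(n = 30, n_snps = 100, seed = 4)
  M <- G$dosages
  M[2, ] <- M[1, ]
  K <- centered_kinship(M)
  expect_equal(K$K[1, ], K$K[2, ], tolerance = 1e-12)
  expect_equal(K$K[1, 2], K$K[1, 1], tolerance = 1e-12)
})

test_that("all-missing SNP columns are dropped with a warning", {
  G <- small_panel(n = 20, n_snps = 50, seed = 5)
  M <- G$dosages
  M[, 3] <- NA
  expect_warning(K <- centered_kinship(M), "all-missing")
  expect_equal(dim(K$K), c(20, 20))
})

test_that("PCA scores are orthogonal and separate subpopulations", {
  G <- small_panel(n = 80, n_snps = 1000, fst = 0.2, seed = 6)
  pcs <- genotype_pca(G, 3)
  xp <- crossprod(pcs)
  expect_lt(max(abs(xp[upper.tri(xp)])) / max(diag(xp)), 1e-8)
  g1 <- pcs[G$subpop == "A", 1]; g2 <- pcs[G$subpop == "B", 1]
  pooled <- sqrt((stats::var(g1) + stats::var(g2)) / 2)
  expect_gt(abs(mean(g1) - mean(g2)) / pooled, 2)
  # zero-variance markers contribute nothing
  M2 <- cbind(G$dosages, z1 = 2L, z2 = 2L)
  expect_equal(abs(genotype_pca(M2, 2)), abs(genotype_pca(G$dosages, 2)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(genotype_pca(G, 80), "n_pcs")
  expect_equal(ncol(genotype_pca(G, 0)), 0)
})

test_that("panel subsetting removes monomorphic SNPs and flags rare alleles", {
  G <- small_panel(n = 50, n_snps = 300, seed = 7)
  pd <- panel_def("All", rownames(G$dosages), 0)
  Gp <- subset_panel(G, pd, min_alt_carriers = 6)
  expect_true(all(apply(Gp$dosages, 2, function(x) length(unique(x))) > 1))
  st <- with(Gp$map, rare_flag)
  n_alt_direct <- pmin(colSums(Gp$dosages == 2), colSums(Gp$dosages == 0))
  expect_equal(unname(st), unname(n_alt_direct < 6))
  expect_error(panel_def("empty", character(0)), "empty")
  expect_error(subset_panel(G, panel_def("X", c("NOPE"))), "not genotyped")
})

test_that("default panels mirror the subspecies composition rules", {
  subpop <- stats::setNames(
    rep(c("AUS", "IND", "TEJ", "TRJ", "ARO", "ADMIX"),
        c(30, 54, 29, 28, 6, 20)), sprintf("ACC%03d", 1:167))
  adm <- c(rep("IND/AUS", 5), rep("TEJ/TRJ", 8), rep("IND/TEJ", 7))
  pl <- default_panels(subpop, adm)
  expect_equal(length(pl$INDAUS$members), 30 + 54 + 5)
  expect_equal(length(pl$JAP$members), 29 + 28 + 8)
  expect_equal(length(pl$All$members), 167)
  expect_equal(pl$All$n_pcs, 3)
  expect_equal(pl$INDAUS$n_pcs, 2)
  expect_equal(pl$TEJ$n_pcs, 0)
})

test_that("allele stats reproduce published carrier arithmetic and ties", {
  ref <- ref_qtl_table()
  for (q in c("qSi1-1", "qAs1-1", "qStHD9-1")) {
    row <- ref[ref$qtl == q, ]
    expect_equal(pct_alt(row$n_common, row$n_alt),
                 c(`qSi1-1` = 25.29, `qAs1-1` = 43.40,
                   `qStHD9-1` = 45.33)[[q]])
  }
  expect_equal(pct_alt(10, 0), 0)
  # tie on carrier counts resolved to the lexicographically smaller base
  M <- matrix(c(0L, 0L, 2L, 2L), ncol = 1,
              dimnames = list(paste0("a", 1:4), "s1"))
  G <- structure(list(dosages = M,
                      map = data.frame(snp = "s1", chr = 1, pos = 10,
                                       ref = "T", alt = "C"),
                      subpop = NULL, inbred = TRUE),
                 class = "genotype_matrix")
  st <- allele_stats(G, "s1")
  expect_equal(st$common_allele, "C")
  expect_equal(st$n_common, 2)
  expect_equal(st$pct_alt, 50)
})

test_that("MLM with K = I equals the OLS F test", {
  G <- small_panel(n = 60, n_snps = 150, seed = 8)
  Gp <- subset_panel(G, panel_def("All", rownames(G$dosages), 0))
  set.seed(1)
  y <- stats::setNames(stats::rnorm(60), rownames(G$dosages))
  KI <- diag(60)
  dimnames(KI) <- list(rownames(G$dosages), rownames(G$dosages))
  a <- mlm_scan(Gp, y, KI)
  o <- ols_scan(Gp, y)
  expect_lt(max(abs(10^(-a$minus_log10_p) - 10^(-o$minus_log10_p))), 1e-6)
})

test_that("effect orientation flips with the common allele, pct_alt does not", {
  G <- small_panel(n = 60, n_snps = 100, seed = 10)
  Gp <- subset_panel(G, panel_def("All", rownames(G$dosages), 0))
  K <- centered_kinship(Gp)
  set.seed(2)
  y <- stats::setNames(stats::rnorm(60) + Gp$dosages[, 5], rownames(G$dosages))
  a1 <- mlm_scan(Gp, y, K)
  # relabel ref/alt and invert dosages for a few SNPs: the common allele
  # base changes but the physical genotypes are identical
  G2 <- Gp
  flip <- c(3, 5, 8)
  G2$dosages[, flip] <- 2L - G2$dosages[, flip]
  tmp <- G2$map$ref[flip]
  G2$map$ref[flip] <- G2$map$alt[flip]
  G2$map$alt[flip] <- tmp
  a2 <- mlm_scan(G2, y, K)
  expect_equal(a2$effect_common, a1$effect_common, tolerance = 1e-8)
  expect_equal(a2$pct_alt, a1$pct_alt)
  expect_equal(a2$minus_log10_p, a1$minus_log10_p, tolerance = 1e-8)
})

test_that("scan results are independent of SNP order", {
  G <- small_panel(n = 50, n_snps = 80, seed = 11)
  Gp <- subset_panel(G, panel_def("All", rownames(G$dosages), 0))
  K <- centered_kinship(Gp)
  set.seed(3)
  y <- stats::setNames(stats::rnorm(50), rownames(G$dosages))
  a1 <- mlm_scan(Gp, y, K)
  perm <- sample(ncol(Gp$dosages))
  G2 <- Gp
  G2$dosages <- G2$dosages[, perm]
  G2$map <- G2$map[perm, ]
  a2 <- mlm_scan(G2, y, K)
  a2 <- a2[match(a1$snp, a2$snp), ]
  expect_equal(a2$minus_log10_p, a1$minus_log10_p, tolerance = 1e-9)
})

test_that("collinear covariates are dropped with a warning", {
  G <- small_panel(n = 40, n_snps = 50, seed = 13)
  Gp <- subset_panel(G, panel_def("All", rownames(G$dosages), 0))
  K <- centered_kinship(Gp)
  set.seed(5)
  y <- stats::setNames(stats::rnorm(40), rownames(G$dosages))
  cv <- cbind(a = stats::rnorm(40), b = 1)   # b collinear with intercept
  rownames(cv) <- rownames(G$dosages)
  expect_warning(a <- mlm_scan(Gp, y, K, covariates = cv), "collinear")
  expect_equal(nrow(a), ncol(Gp$dosages))
})
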