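# Variance components, BLUP shrinkage, LSmeans, log transform, correlations.

test_that("balanced one-way REML matches the analytic shrinkage formula", {
  for (s in 1:5) {
    d <- balanced_records(n = 30, r = 2, sigma_a = 1, sigma_e = 1, seed = s)
    f <- fit_two_level_reml(d, "y", use_env = FALSE)
    an <- anova_oneway(d)
    expect_equal(unname(f$varcomp["accession"]), an$s_a, tolerance = 1e-8)
    expect_equal(unname(f$varcomp["residual"]), an$s_e, tolerance = 1e-8)
    expected <- (an$s_a / (an$s_a + an$s_e / an$r)) *
      (an$ybar - mean(an$ybar))
    expect_equal(f$blups[names(expected)],
                 stats::setNames(as.numeric(expected), names(expected)),
                 tolerance = 1e-8)
    # shrinkage property: |BLUP| never exceeds the raw deviation
    expect_true(all(abs(f$blups[names(expected)]) <=
                      abs(an$ybar - mean(an$ybar)) + 1e-12))
  }
})

test_that("sigma_a = sigma_e with r = 2 gives the 2/3 shrinkage factor", {
  # construct data whose ANOVA estimators are exactly sigma_a = sigma_e by
  # checking the factor implied by the estimates rather than the truth
  d <- balanced_records(n = 50, r = 2, seed = 42)
  f <- fit_two_level_reml(d, "y", use_env = FALSE)
  an <- anova_oneway(d)
  k <- as.numeric(f$blups / (an$ybar[names(f$blups)] - mean(an$ybar)))
  k <- k[is.finite(k)]
  expect_equal(k, rep(an$s_a / (an$s_a + an$s_e / 2), length(k)),
               tolerance = 1e-7)
})

test_that("identical replicates give zero residual and unshrunken BLUPs", {
  d <- balanced_records(n = 12, r = 3, sigma_e = 0, seed = 3)
  f <- fit_two_level_reml(d, "y", use_env = FALSE)
  expect_equal(unname(f$varcomp["residual"]), 0)
  ybar <- tapply(d$value, d$accession, mean)
  expect_equal(f$blups[names(ybar)],
               stats::setNames(as.numeric(ybar - mean(ybar)), names(ybar)),
               tolerance = 1e-10)
})

test_that("zero-variance trait warns and returns all-zero BLUPs", {
  d <- balanced_records(n = 8, r = 2, sigma_a = 0, sigma_e = 0, seed = 1)
  d$value <- 7
  expect_warning(f <- fit_two_level_reml(d, "y", use_env = FALSE),
                 "zero total variance")
  expect_true(all(f$blups == 0))
})

test_that("REML recovers planted variance components", {
  # sigma2_a = 2, sigma2_e = 1, n = 200, r = 4
  est <- matrix(NA_real_, 20, 2)
  for (s in 1:20) {
    set.seed(1000 + s)
    acc <- sprintf("A%03d", 1:200)
    a <- stats::rnorm(200, 0, sqrt(2))
    d <- expand.grid(accession = acc, env = "E1", rep = 1:4, trait = "y",
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    d$value <- 5 + a[match(d$accession, acc)] + stats::rnorm(nrow(d))
    f <- fit_two_level_reml(d, "y", use_env = FALSE)
    est[s, ] <- f$varcomp[c("accession", "residual")]
  }
  expect_lt(abs(mean(est[, 1]) - 2) / 2, 0.25)
  expect_lt(abs(mean(est[, 2]) - 1) / 1, 0.25)
})

test_that("environment variance is separated when environments repeat", {
  set.seed(9)
  acc <- sprintf("A%02d", 1:60)
  envs <- sprintf("E%d", 1:8)
  a <- stats::rnorm(60, 0, 1)
  e <- stats::rnorm(8, 0, 2)
  d <- expand.grid(accession = acc, env = envs, rep = 1:2, trait = "y",
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$value <- a[match(d$accession, acc)] + e[match(d$env, envs)] +
    stats::rnorm(nrow(d), 0, 0.5)
  f <- fit_two_level_reml(d, "y")
  expect_gt(f$varcomp["environment"], 0.5)
  expect_lt(abs(f$varcomp["accession"] - 1), 0.6)
})

test_that("lsmeans equal accession means for balanced data and are
           translation-stable across environments", {
  set.seed(4)
  acc <- sprintf("A%02d", 1:10)
  d <- expand.grid(accession = acc, env = c("E1", "E2"), rep = 1:2,
                   trait = "y", KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$value <- stats::rnorm(nrow(d))
  ls1 <- lsmeans(d, "y")
  expect_equal(ls1, tapply(d$value, d$accession, mean)[names(ls1)],
               tolerance = 1e-10, ignore_attr = TRUE)
  d2 <- d
  d2$value[d2$env == "E2"] <- d2$value[d2$env == "E2"] + 10
  ls2 <- lsmeans(d2, "y")
  expect_equal(ls2 - mean(ls2), ls1 - mean(ls1), tolerance = 1e-10)
})

test_that("unbalanced lsmeans match a direct normal-equations oracle", {
  # 3 accessions x 2 envs, one cell missing entirely for accession C
  d <- data.frame(
    accession = c("A", "A", "B", "B", "C", "A", "B"),
    env = c("E1", "E1", "E1", "E1", "E1", "E2", "E2"),
    rep = c(1, 2, 1, 2, 1, 1, 1), trait = "y",
    value = c(10, 12, 8, 9, 20, 15, 11), stringsAsFactors = FALSE)
  expect_warning(ls <- lsmeans(d, "y"), "absent")
  # oracle: solve X'X b = X'y with sum-contrast env column
  acc <- factor(d$accession); env <- factor(d$env)
  X <- cbind(stats::model.matrix(~ 0 + acc),
             ifelse(env == "E1", 1, -1))
  b <- solve(crossprod(X), crossprod(X, d$value))
  expect_equal(unname(ls["A"]), b[1], tolerance = 1e-10)
  expect_equal(unname(ls["B"]), b[2], tolerance = 1e-10)
  expect_equal(unname(ls["C"]), 20)  # fallback: mean over available cells
})

test_that("log transform obeys log laws, rejects nonpositives, reduces skew", {
  expect_equal(as.numeric(log_transform(1)), 0)
  expect_equal(as.numeric(log_transform(exp(1))), 1)
  expect_error(log_transform(c(2, 0, 1), "As"), "As")
  set.seed(8)
  x <- exp(stats::rnorm(500))
  sk <- function(v) abs(mean((v - mean(v))^3) / stats::sd(v)^3)
  expect_lt(sk(as.numeric(log_transform(x))), sk(x))
})

test_that("pearson_with_t matches hand arithmetic and cor.test", {
  x <- c(1.2, 2.4, 3.1, 4.8, 5.0, 6.1, 7.7, 8.2, 9.9, 10.3)
  y <- c(2.0, 1.8, 3.9, 4.1, 6.2, 5.8, 7.1, 9.0, 8.8, 11.2)
  ct <- pearson_with_t(x, y)
  # hand covariance formula
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ct$r, r_hand, tolerance = 1e-12)
  base <- stats::cor.test(x, y)
  expect_equal(ct$r, unname(base$estimate), tolerance = 1e-12)
  expect_equal(ct$p, base$p.value, tolerance = 1e-12)
  expect_equal(pearson_with_t(x, 2 * x)$r, 1)
  expect_warning(res <- pearson_with_t(x, rep(1, 10)), "zero-variance")
  expect_true(is.na(res$r))
})

test_that("independent data give approximately uniform p-values", {
  set.seed(21)
  p <- replicate(300, pearson_with_t(stats::rnorm(50), stats::rnorm(50))$p)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.001)
  expect_lt(abs(mean(p < 0.1) - 0.1), 0.06)
})

test_that("trait matrix is one row per accession with symmetric correlations", {
  G <- small_panel(n = 50, n_snps = 60, seed = 12)
  recs <- simulate_traits(G, default_truth(G), seed = 2)
  tm <- trait_matrix(recs)
  expect_equal(nrow(tm), 50)
  expect_equal(sort(colnames(tm)), sort(default_truth()$traits))
  expect_equal(unname(attr(tm, "transform")["As"]), "log")
  expect_equal(unname(attr(tm, "transform")["DHDnt"]), "identity")
  cm <- correlation_matrix(tm)
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, ncol(tm)))
  expect_true(all(cm$r >= -1 & cm$r <= 1))
})
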