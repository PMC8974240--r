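# Kinship, PCA covariates, panel subsetting, and per-SNP mixed-linear-model
# association scans. The MLM is the EMMA-style eigendecomposition form: one
# eigendecomposition of the kinship per panel, then a 1-D REML optimisation
# of the genetic/residual variance ratio for every marker.

#' Centered genotype kinship matrix
#'
#' VanRaden-style centered cross-product: `K = C C' / s` where `C` is the
#' column-centered dosage matrix (missing values mean-imputed per SNP before
#' centering) and `s` is the sum of the per-SNP dosage variances (equivalently
#' the mean column variance times the SNP count). Rows and columns sum to
#' zero; monomorphic SNPs contribute nothing.
#'
#' @param G a `genotype_matrix` or a plain accession x SNP dosage matrix
#' @return list of class `kinship` with `K` (symmetric matrix) and `scale`
#' @export
centered_kinship <- function(G) {
  M <- if (inherits(G, "genotype_matrix")) G$dosages else G
  if (nrow(M) < 2) stopf("need >= 2 accessions for kinship")
  M <- impute_mean(M)
  allna <- attr(M, "dropped")
  if (length(allna)) warnf("dropped %d all-missing SNP columns", length(allna))
  C <- scale(M, center = TRUE, scale = FALSE)
  v <- colSums(C^2) / nrow(C)
  s <- sum(v)
  if (s <= 0) stopf("all SNPs monomorphic: kinship undefined")
  K <- tcrossprod(C) / s
  structure(list(K = K, scale = s), class = "kinship")
}

# mean-impute missing dosages per SNP; drop all-missing columns
impute_mean <- function(M) {
  dropped <- integer(0)
  if (anyNA(M)) {
    cm <- colMeans(M, na.rm = TRUE)
    dropped <- which(!is.finite(cm))
    if (length(dropped)) {
      M <- M[, -dropped, drop = FALSE]
      cm <- cm[-dropped]
    }
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- cm[idx[, 2]]
  }
  attr(M, "dropped") <- dropped
  M
}

#' Principal component scores of the centered dosage matrix
#'
#' @param G a `genotype_matrix` or dosage matrix
#' @param n_pcs number of components; `0` returns a zero-column matrix
#' @return accession x n_pcs score matrix (orthogonal columns)
#' @export
genotype_pca <- function(G, n_pcs) {
  M <- if (inherits(G, "genotype_matrix")) G$dosages else G
  if (n_pcs <= 0) return(matrix(0, nrow(M), 0, dimnames = list(rownames(M), NULL)))
  if (n_pcs >= nrow(M)) stopf("n_pcs must be < number of accessions")
  M <- impute_mean(M)
  C <- scale(M, center = TRUE, scale = FALSE)
  sv <- svd(C, nu = n_pcs, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  dimnames(scores) <- list(rownames(M), paste0("PC", seq_len(n_pcs)))
  scores
}

#' Panel definition
#' @param name panel name (e.g. All, INDAUS, JAP, IND, AUS, TEJ, TRJ)
#' @param members accession ids
#' @param n_pcs principal component covariates for this panel
#' @return object of class `panel_def`
#' @export
panel_def <- function(name, members, n_pcs = 0) {
  if (!length(members)) stopf("empty panel '%s'", name)
  if (n_pcs < 0) stopf("n_pcs must be >= 0")
  structure(list(name = name, members = unique(members), n_pcs = n_pcs),
            class = "panel_def")
}

#' Default panel set for a subpopulation-labelled collection
#'
#' Builds the seven standard panels: All; the indica (IND + AUS + IND/AUS
#' admixed) and japonica (TEJ + TRJ + TEJ/TRJ admixed) subspecies; and the
#' four subpopulations. PC covariate counts default to All = 3, INDAUS = 2,
#' JAP = 1, IND = 1, TEJ = TRJ = AUS = 0.
#'
#' @param subpop named vector accession -> subpopulation label
#' @param admix_parents optional parent-pair strings ("IND/AUS") for
#'   accessions labelled `ADMIX`, used to place admixed members in subspecies
#' @param n_pcs named overrides of the per-panel PC counts
#' @return named list of [panel_def()]s
#' @export
default_panels <- function(subpop, admix_parents = NULL,
                           n_pcs = c(All = 3, INDAUS = 2, JAP = 1, IND = 1,
                                     AUS = 0, TEJ = 0, TRJ = 0)) {
  acc <- names(subpop)
  adm <- acc[subpop == "ADMIX"]
  pair <- stats::setNames(rep("", length(adm)), adm)
  if (length(adm) && !is.null(admix_parents) && length(admix_parents) == length(adm))
    pair[] <- admix_parents
  in_pair <- function(groups) adm[vapply(pair, function(p) {
    ps <- strsplit(p, "/", fixed = TRUE)[[1]]
    length(ps) && all(ps %in% groups)
  }, TRUE)]
  sets <- list(
    All = acc,
    INDAUS = c(acc[subpop %in% c("IND", "AUS")], in_pair(c("IND", "AUS"))),
    JAP = c(acc[subpop %in% c("TEJ", "TRJ")], in_pair(c("TEJ", "TRJ"))),
    IND = acc[subpop == "IND"],
    AUS = acc[subpop == "AUS"],
    TEJ = acc[subpop == "TEJ"],
    TRJ = acc[subpop == "TRJ"])
  sets <- sets[vapply(sets, length, 0L) > 0]
  out <- lapply(names(sets), function(nm)
    panel_def(nm, sets[[nm]], unname(n_pcs[nm] %||% 0)))
  stats::setNames(out, names(sets))
}

#' Restrict a genotype matrix to a panel
#'
#' Keeps the panel's accessions, removes SNPs monomorphic within the panel,
#' and flags (keeps) SNPs whose alternate homozygote is carried by fewer than
#' `min_alt_carriers` members; the flag feeds the region caller's rare-allele
#' stringency filter.
#'
#' @param G a `genotype_matrix`
#' @param panel a [panel_def()]
#' @param min_alt_carriers rare-allele carrier threshold (default 6)
#' @return a `genotype_matrix` with attribute columns `rare_flag` on the map
#' @export
subset_panel <- function(G, panel, min_alt_carriers = 6) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(panel, "panel_def"))
  miss <- setdiff(panel$members, rownames(G$dosages))
  if (length(miss)) stopf("panel members not genotyped: %s",
                          paste(utils::head(miss, 3), collapse = ", "))
  D <- G$dosages[panel$members, , drop = FALSE]
  poly <- apply(D, 2, function(x) length(unique(x[!is.na(x)])) > 1)
  D <- D[, poly, drop = FALSE]
  map <- G$map[poly, , drop = FALSE]
  st <- allele_stats_matrix(D, map)
  map$rare_flag <- st$n_alt < min_alt_carriers
  structure(list(dosages = D, map = map,
                 subpop = G$subpop[panel$members],
                 inbred = G$inbred, panel = panel$name),
            class = "genotype_matrix")
}

# vectorised allele stats over all SNP columns of a dosage matrix
allele_stats_matrix <- function(D, map) {
  n2 <- colSums(D == 2, na.rm = TRUE)   # homozygous alt carriers
  n0 <- colSums(D == 0, na.rm = TRUE)   # homozygous ref carriers
  alt_common <- n2 > n0 | (n2 == n0 & map$alt < map$ref)  # tie: smaller base
  data.frame(
    common_allele = ifelse(alt_common, map$alt, map$ref),
    alt_allele = ifelse(alt_common, map$ref, map$alt),
    n_common = ifelse(alt_common, n2, n0),
    n_alt = ifelse(alt_common, n0, n2),
    common_is_alt = alt_common,
    stringsAsFactors = FALSE)
}

#' Allele identities and carrier counts at one SNP
#'
#' Counts accessions homozygous for each allele among non-missing members.
#' The common allele is the one carried by more accessions (ties broken by
#' the lexicographically smaller base); `pct_alt` is
#' `100 * n_alt / (n_common + n_alt)` rounded to 2 decimals.
#'
#' @param G a `genotype_matrix`
#' @param snp SNP id (column name)
#' @param members optional accession subset
#' @return list: common_allele, alt_allele, n_common, n_alt, pct_alt
#' @export
allele_stats <- function(G, snp, members = NULL) {
  j <- match(snp, G$map$snp)
  if (is.na(j)) stopf("unknown SNP '%s'", snp)
  D <- G$dosages[, j, drop = FALSE]
  if (!is.null(members)) D <- D[members, , drop = FALSE]
  st <- allele_stats_matrix(D, G$map[j, , drop = FALSE])
  list(common_allele = st$common_allele, alt_allele = st$alt_allele,
       n_common = st$n_common, n_alt = st$n_alt,
       pct_alt = pct_alt(st$n_common, st$n_alt))
}

# Per-marker REML criterion pieces on the eigenrotated scale.
# Given delta = sigma2_e / sigma2_g... we parameterise V = sigma2 (delta*K + I)
# no: V = sigma2_g K + sigma2_e I = sigma2_e (lambda K + I), lambda = g/e.
# With K = U diag(xi) U', weights are 1/(lambda*xi + 1).
# Restricted LL (dropping constants):
#   -0.5 [ (n-q)*(log(RSS) - log(n-q) + 1) + sum log(lambda xi + 1)
#          + log det(W' D W) ]
# where W = [X, x] rotated, D = diag(1/(lambda xi + 1)), RSS the weighted RSS.
reml_marker_crit <- function(loglam, yr, Wr, xi) {
  lam <- exp(loglam)
  w <- 1 / (lam * xi + 1)
  sw <- sqrt(w)
  Ww <- Wr * sw
  yw <- yr * sw
  qr_ <- qr(Ww)
  res <- qr.resid(qr_, yw)
  rss <- sum(res^2)
  n <- length(yr); q <- ncol(Wr)
  R <- qr.R(qr_)
  ldet <- 2 * sum(log(abs(diag(R))))
  -0.5 * ((n - q) * (log(rss) - log(n - q) + 1) + sum(log(lam * xi + 1)) + ldet)
}

#' Mixed-linear-model association scan
#'
#' Fits, for every SNP, `y = mu + covariates + snp + u + e` with
#' `u ~ N(0, s2_g K)` and `e ~ N(0, s2_e I)`. The kinship is eigendecomposed
#' once; the genetic-to-residual variance ratio is re-estimated for each
#' marker by REML (coarse log-spaced grid followed by Brent refinement), and
#' the marker is tested with the F statistic (Wald chi-square optional). The
#' reported effect is oriented to the panel's most common allele.
#'
#' @param G a `genotype_matrix` (typically from [subset_panel()])
#' @param y named trait vector aligned (by name) to the panel accessions
#' @param K a [centered_kinship()] result (or symmetric matrix)
#' @param covariates optional accession x q covariate matrix (PCs)
#' @param trait,panel labels carried into the output
#' @param n_grid coarse grid size over `log(lambda)` (default 64)
#' @param refine_tol Brent tolerance on `log(lambda)` (default 1e-8)
#' @param statistic `"F"` (default) or `"wald"`
#' @return data.frame of class `assoc_records`: snp, chr, pos, minus_log10_p,
#'   effect_common, common_allele, alt_allele, n_common, n_alt, pct_alt,
#'   rare_flag, trait, panel
#' @export
mlm_scan <- function(G, y, K, covariates = NULL, trait = "trait",
                     panel = "panel", n_grid = 64, refine_tol = 1e-8,
                     statistic = c("F", "wald")) {
  statistic <- match.arg(statistic)
  M <- impute_mean(G$dosages)
  acc <- rownames(M)
  if (!is.null(names(y))) y <- y[acc]
  Km <- if (inherits(K, "kinship")) K$K else K
  if (!is.null(rownames(Km))) Km <- Km[acc, acc]
  if (anyNA(y)) {
    keep <- !is.na(y)
    M <- M[keep, , drop = FALSE]; acc <- acc[keep]; y <- y[keep]
    Km <- Km[keep, keep]
  }
  n <- length(y)
  X <- matrix(1, n, 1)
  if (!is.null(covariates) && ncol(covariates) > 0) {
    cv <- covariates[acc, , drop = FALSE]
    X <- cbind(X, cv)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      warnf("dropping %d collinear covariate column(s)", ncol(X) - qrX$rank)
      X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    }
  }
  p <- ncol(X)

  eig <- eigen(Km + diag(1e-8, n), symmetric = TRUE)
  xi <- pmax(eig$values, 0)
  U <- eig$vectors
  yr <- drop(crossprod(U, y))
  Xr <- crossprod(U, X)
  Gr <- crossprod(U, M)
  m <- ncol(M)

  # coarse grid, vectorised across markers via the Schur complement:
  # det(W'DW) = det(X'DX) * ||r_x||^2 where r_x is x residualised on X
  grid <- seq(log(1e-5), log(1e5), length.out = n_grid)
  best_ll <- rep(-Inf, m); best_g <- rep(grid[1], m)
  for (lg in grid) {
    lam <- exp(lg)
    w <- 1 / (lam * xi + 1); sw <- sqrt(w)
    Xw <- Xr * sw; yw <- yr * sw; Gw <- Gr * sw
    qrX <- qr(Xw)
    Q <- qr.Q(qrX)
    ry <- qr.resid(qrX, yw)
    RG <- Gw - Q %*% crossprod(Q, Gw)
    ldX <- 2 * sum(log(abs(diag(qr.R(qrX)))))
    xx <- colSums(RG^2)
    xy <- drop(crossprod(RG, ry))
    rss <- pmax(sum(ry^2) - xy^2 / pmax(xx, 1e-300), 1e-300)
    ll <- -0.5 * ((n - p - 1) * (log(rss) - log(n - p - 1) + 1) +
                    sum(log(lam * xi + 1)) + ldX + log(pmax(xx, 1e-300)))
    upd <- ll > best_ll & xx > 1e-12
    best_ll[upd] <- ll[upd]; best_g[upd] <- lg
  }

  step <- diff(grid[1:2])
  out <- data.frame(snp = G$map$snp, chr = G$map$chr, pos = G$map$pos,
                    minus_log10_p = NA_real_, effect_common = NA_real_,
                    stringsAsFactors = FALSE)
  logp <- numeric(m); beta <- numeric(m)
  for (j in seq_len(m)) {
    Wr <- cbind(Xr, Gr[, j])
    o <- stats::optimize(reml_marker_crit, yr = yr, Wr = Wr, xi = xi,
                         lower = best_g[j] - step, upper = best_g[j] + step,
                         maximum = TRUE, tol = refine_tol)
    lam <- exp(o$maximum)
    w <- 1 / (lam * xi + 1); sw <- sqrt(w)
    Ww <- Wr * sw; yw <- yr * sw
    fit <- stats::lm.fit(Ww, yw)
    rss1 <- sum(fit$residuals^2)
    rss0 <- sum(qr.resid(qr(Xr * sw), yw)^2)
    df2 <- n - p - 1
    b <- fit$coefficients[p + 1]
    if (!is.finite(b)) { logp[j] <- 0; beta[j] <- NA_real_; next }
    if (statistic == "F") {
      Fs <- max(0, (rss0 - rss1)) / (rss1 / df2)
      pv <- stats::pf(Fs, 1, df2, lower.tail = FALSE)
    } else {
      s2 <- rss1 / df2
      XtXi <- chol2inv(qr.R(qr(Ww)))
      se <- sqrt(s2 * XtXi[p + 1, p + 1])
      pv <- 2 * stats::pnorm(abs(b / se), lower.tail = FALSE)
    }
    logp[j] <- -log10(max(pv, 1e-300))
    beta[j] <- b
  }
  st <- allele_stats_matrix(G$dosages, G$map)
  # beta is the per-copy effect of the alt allele (dosage counts alt copies);
  # flip when the panel's most common allele is the reference allele
  out$minus_log10_p <- logp
  out$effect_common <- ifelse(st$common_is_alt, beta, -beta)
  out$common_allele <- st$common_allele
  out$alt_allele <- st$alt_allele
  out$n_common <- st$n_common
  out$n_alt <- st$n_alt
  out$pct_alt <- pct_alt(st$n_common, st$n_alt)
  out$rare_flag <- G$map$rare_flag %||% (st$n_alt < 6)
  out$trait <- trait
  out$panel <- panel
  class(out) <- c("assoc_records", "data.frame")
  out
}

#' Ordinary least-squares scan (no kinship correction)
#'
#' The naive baseline used to demonstrate that the mixed model controls
#' structure-driven inflation.
#'
#' @inheritParams mlm_scan
#' @return data.frame with snp, chr, pos, minus_log10_p, effect_alt
#' @export
ols_scan <- function(G, y, covariates = NULL) {
  M <- impute_mean(G$dosages)
  acc <- rownames(M)
  if (!is.null(names(y))) y <- y[acc]
  n <- length(y)
  X <- matrix(1, n, 1)
  if (!is.null(covariates) && ncol(covariates) > 0)
    X <- cbind(X, covariates[acc, , drop = FALSE])
  p <- ncol(X)
  qrX <- qr(X)
  ry <- qr.resid(qrX, y)
  RG <- qr.resid(qrX, M)
  xx <- colSums(RG^2)
  xy <- drop(crossprod(RG, ry))
  b <- xy / pmax(xx, 1e-300)
  rss1 <- pmax(sum(ry^2) - xy^2 / pmax(xx, 1e-300), 1e-300)
  df2 <- n - p - 1
  Fs <- pmax(0, sum(ry^2) - rss1) / (rss1 / df2)
  pv <- stats::pf(Fs, 1, df2, lower.tail = FALSE)
  data.frame(snp = G$map$snp, chr = G$map$chr, pos = G$map$pos,
             minus_log10_p = -log10(pmax(pv, 1e-300)), effect_alt = b,
             stringsAsFactors = FALSE)
}

#' Genomic-control inflation factor
#'
#' Median chi-square statistic implied by the p-values divided by the null
#' median `qchisq(0.5, 1)`.
#'
#' @param minus_log10_p vector of -log10 p-values
#' @return lambda_GC
#' @export
inflation_factor <- function(minus_log10_p) {
  chisq <- stats::qchisq(10^(-minus_log10_p), df = 1, lower.tail = FALSE)
  stats::median(chisq, na.rm = TRUE) / stats::qchisq(0.5, 1)
}
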