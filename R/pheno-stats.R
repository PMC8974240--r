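# Replicated raw phenotypes -> variance components, BLUPs, LSmeans,
# log transform of skewed element traits, and Pearson correlations.

# Restricted log-likelihood and derived quantities for
#   y = X b + sum_k Z_k u_k + e,  u_k ~ N(0, s_k I),  e ~ N(0, s0 I)
# computed through the Woodbury identity so cost scales with the number of
# random-effect levels, not records.
reml_pieces <- function(y, X, Zs, s) {
  n <- length(y); p <- ncol(X)
  s0 <- s[1]; sk <- s[-1]
  q <- vapply(Zs, ncol, 0L)
  Z <- do.call(cbind, Zs)
  Dinv <- rep(1 / sk, q)
  M <- diag(Dinv, nrow = ncol(Z)) + crossprod(Z) / s0
  cM <- chol(M)
  Vinv <- function(A) {
    # V^{-1} A with V = s0 I + Z D Z'
    ZtA <- crossprod(Z, A)
    (A - Z %*% backsolve(cM, forwardsolve(t(cM), ZtA / s0))) / s0
  }
  ViX <- Vinv(X); Viy <- Vinv(y)
  XtViX <- crossprod(X, ViX)
  cX <- chol(XtViX)
  bhat <- backsolve(cX, forwardsolve(t(cX), crossprod(X, Viy)))
  Py <- Viy - ViX %*% bhat
  ldV <- n * log(s0) + 2 * sum(log(diag(cM))) + sum(q * log(sk))
  ldX <- 2 * sum(log(diag(cX)))
  ll <- -0.5 * (ldV + ldX + sum(y * Py) + (n - p) * log(2 * pi))
  list(Py = Py, Vinv = Vinv, ViX = ViX, XtViX = XtViX, cX = cX,
       bhat = bhat, ll = ll, Z = Z, q = q)
}

# P A = V^{-1}A - V^{-1}X (X'V^{-1}X)^{-1} X'V^{-1} A
apply_P <- function(pieces, A) {
  ViA <- pieces$Vinv(A)
  ViA - pieces$ViX %*% backsolve(pieces$cX,
        forwardsolve(t(pieces$cX), crossprod(pieces$ViX, A)))
}

# AI-REML for variance components; theta = (s0, s1, ..., sK).
# Average-information Newton steps with EM fallback when a step leaves the
# parameter space; converges on the gradient, which is what gives the
# closed-form agreement at 1e-8 in balanced designs.
ai_reml <- function(y, X, Zs, tol = 1e-10, max_iter = 200) {
  n <- length(y); p <- ncol(X); K <- length(Zs)
  vy <- stats::var(y)
  if (vy < .Machine$double.eps) {
    return(list(s = c(resid = 0, rep(0, K)), ll = NA_real_, converged = TRUE,
                zero_variance = TRUE))
  }
  theta <- c(vy / 2, rep(vy / (2 * K), K))
  floor_v <- vy * 1e-10
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    pieces <- reml_pieces(y, X, Zs, theta)
    Py <- pieces$Py
    # gradient: dl/ds_k = -0.5 (tr(P V_k) - y'P V_k P y), with V_0 = I
    PI <- apply_P(pieces, diag(n))        # dense P; n is a few hundred here
    trPV <- numeric(K + 1)
    trPV[1] <- sum(diag(PI))
    for (k in seq_len(K)) trPV[k + 1] <- sum(Zs[[k]] * (PI %*% Zs[[k]]))
    yPVPy <- numeric(K + 1)
    yPVPy[1] <- sum(Py * Py)
    for (k in seq_len(K)) yPVPy[k + 1] <- sum(crossprod(Zs[[k]], Py)^2)
    grad <- -0.5 * (trPV - yPVPy)
    if (max(abs(grad)) < tol * max(1, abs(pieces$ll)) ||
        (iter > 1 && abs(pieces$ll - ll_old) < 1e-13 * max(1, abs(pieces$ll)) &&
         max(abs(grad)) < 1e-6)) {
      return(list(s = theta, ll = pieces$ll, converged = TRUE,
                  pieces = pieces, zero_variance = FALSE))
    }
    ll_old <- pieces$ll
    # average information matrix: AI_kl = 0.5 y'P V_k P V_l P y
    # columns of Wm are V_k P y, with V_0 = I
    Wm <- cbind(Py, do.call(cbind, lapply(seq_len(K), function(k)
      Zs[[k]] %*% crossprod(Zs[[k]], Py))))
    PW <- apply_P(pieces, Wm)
    AI <- 0.5 * crossprod(Wm, PW)
    step <- tryCatch(solve(AI, grad), error = function(e) grad / diag(AI))
    cand <- theta + step
    if (any(!is.finite(cand)) || any(cand < floor_v)) {
      # EM fallback: s_k <- s_k + s_k^2 (y'P V_k P y - tr(P V_k)) / w_k
      w <- c(n - p, vapply(Zs, ncol, 0L))
      cand <- theta + theta^2 * (yPVPy - trPV) / w
      cand <- pmax(cand, floor_v)
    }
    theta <- cand
  }
  list(s = theta, ll = pieces$ll, converged = FALSE, pieces = pieces,
       zero_variance = FALSE)
}

#' REML variance components and BLUPs from replicated phenotypes
#'
#' Fits a Gaussian mixed model with a random accession intercept, optionally a
#' random environment intercept and a random subpopulation block, by average-
#' information REML. Returns per-accession best linear unbiased predictions
#' (BLUPs). In a balanced one-way design the accession BLUP is the familiar
#' shrunken deviation `(s2_a / (s2_a + s2_e / r)) * (ybar_i - ybar)`.
#'
#' @param records long-format phenotypes (columns accession, env, rep, trait,
#'   value), e.g. from [simulate_traits()] or [read_phenotypes()]
#' @param trait trait name to fit
#' @param use_env include a random environment intercept (default `TRUE` when
#'   more than one environment is present)
#' @param blocks optional named vector mapping accession -> subpopulation; if
#'   given, a random block intercept models the nested family structure
#' @param log_transform apply [log_transform()] to the values first
#' @return list with `varcomp` (accession, environment, block, residual),
#'   `blups` (named per accession), `grand_mean`, `method`, `converged`
#' @export
fit_two_level_reml <- function(records, trait, use_env = NULL, blocks = NULL,
                               log_transform = FALSE) {
  d <- records[records$trait == trait, , drop = FALSE]
  if (!nrow(d)) stopf("no records for trait '%s'", trait)
  if (length(unique(d$accession)) < 2) stopf("need >= 2 accessions")
  y <- d$value
  if (log_transform) y <- log_transform(y, trait)
  acc <- factor(d$accession)
  if (is.null(use_env)) use_env <- length(unique(d$env)) > 1

  # degenerate cases first
  if (stats::var(y) < .Machine$double.eps) {
    warnf("trait '%s' has zero total variance; returning all-zero BLUPs", trait)
    return(list(varcomp = c(accession = 0, environment = 0, block = 0,
                            residual = 0),
                blups = stats::setNames(rep(0, nlevels(acc)), levels(acc)),
                grand_mean = mean(y), method = "REML(AI)", converged = TRUE))
  }
  within_var <- stats::ave(y, acc, FUN = stats::var)
  if (all(within_var < 1e-14, na.rm = TRUE) && !use_env && is.null(blocks)) {
    # all replicate values identical per accession: sigma2_resid = 0 and the
    # BLUP is the unshrunken deviation
    mns <- tapply(y, acc, mean)
    return(list(varcomp = c(accession = stats::var(as.numeric(mns)),
                            environment = 0, block = 0, residual = 0),
                blups = stats::setNames(as.numeric(mns - mean(mns)),
                                        names(mns)),
                grand_mean = mean(as.numeric(mns)), method = "REML(AI)",
                converged = TRUE))
  }

  X <- matrix(1, nrow = length(y), ncol = 1)
  Zs <- list(accession = stats::model.matrix(~ 0 + acc))
  if (use_env) {
    env <- factor(d$env)
    Zs$environment <- stats::model.matrix(~ 0 + env)
  }
  if (!is.null(blocks)) {
    blk <- factor(blocks[as.character(d$accession)])
    Zs$block <- stats::model.matrix(~ 0 + blk)
  }
  fit <- ai_reml(y, X, Zs)
  s <- fit$s
  pieces <- fit$pieces %||% reml_pieces(y, X, Zs, s)
  # BLUP: u_k = s_k Z_k' P y
  u_acc <- s[2] * crossprod(Zs$accession, pieces$Py)
  blups <- stats::setNames(as.numeric(u_acc),
                           sub("^acc", "", colnames(Zs$accession)))
  vc <- c(accession = unname(s[2]),
          environment = if (use_env) unname(s[which(names(Zs) == "environment") + 1]) else 0,
          block = if (!is.null(blocks)) unname(s[which(names(Zs) == "block") + 1]) else 0,
          residual = unname(s[1]))
  list(varcomp = vc, blups = blups, grand_mean = as.numeric(pieces$bhat),
       method = "REML(AI)", converged = fit$converged)
}

#' Least-squares (adjusted) accession means
#'
#' Two-way fixed-effects model `value ~ accession + environment` solved by
#' least squares with sum-to-zero environment contrasts, so each LSmean is
#' the accession estimate averaged over environments. For balanced data this
#' equals the plain accession mean. Accessions absent from one or more
#' environments trigger an estimability warning and fall back to the mean
#' over their available cells.
#'
#' @param records long-format phenotypes
#' @param trait trait name
#' @param log_transform apply the natural-log transform first
#' @return named numeric vector of LSmeans per accession
#' @export
lsmeans <- function(records, trait, log_transform = FALSE) {
  d <- records[records$trait == trait, , drop = FALSE]
  if (!nrow(d)) stopf("no records for trait '%s'", trait)
  y <- d$value
  if (log_transform) y <- log_transform(y, trait)
  acc <- factor(d$accession)
  env <- factor(d$env)
  if (nlevels(env) == 1) {
    mns <- tapply(y, acc, mean)
    return(stats::setNames(as.numeric(mns), names(mns)))
  }
  tab <- table(acc, env)
  missing_cells <- rownames(tab)[rowSums(tab == 0) > 0]
  X <- cbind(stats::model.matrix(~ 0 + acc),
             stats::model.matrix(~ env, contrasts.arg =
                                   list(env = stats::contr.sum))[, -1, drop = FALSE])
  cf <- stats::lm.fit(X, y)$coefficients
  out <- stats::setNames(as.numeric(cf[seq_len(nlevels(acc))]), levels(acc))
  if (length(missing_cells)) {
    warnf("accessions absent in some environments (%s); using mean over available cells",
          paste(missing_cells, collapse = ", "))
    for (a in missing_cells) out[a] <- mean(y[acc == a])
  }
  out
}

#' Natural-log transform for right-skewed element concentrations
#'
#' @param values numeric vector, all strictly positive
#' @param trait trait name used in error messages
#' @return log-transformed values with `attr(, "transform") = "log"`
#' @export
log_transform <- function(values, trait = "trait") {
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad))
    stopf("nonpositive value for %s at record %d (value %g): cannot log-transform",
          trait, bad[1], values[bad[1]])
  out <- log(values)
  attr(out, "transform") <- "log"
  out
}

#' Pearson correlation with Student's t-test
#'
#' Two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y paired numeric vectors; pairs with missing values are dropped
#' @return list with `r`, `p`, `n`, `t`
#' @export
pearson_with_t <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stopf("need >= 3 paired observations, got %d", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warnf("zero-variance input: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n, t = NA_real_))
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n, t = Inf))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE),
       n = n, t = tt)
}

#' Accession x trait matrix of BLUPs (or LSmeans)
#'
#' Runs [fit_two_level_reml()] (or [lsmeans()]) per trait and assembles the
#' accession-by-trait matrix that feeds correlations, GWAS, and network
#' learning. Traits tagged `"exp"`/`"log"` in `transform` are natural-log
#' transformed first and tagged `log` in the result.
#'
#' @param records long-format phenotypes
#' @param traits traits to include (default: all present)
#' @param method `"blup"` (default) or `"lsmean"`
#' @param transform named character vector; traits marked `"exp"` or `"log"`
#'   are log-transformed (defaults to `attr(records, "transform")`)
#' @param center_blups add the grand mean back so columns are on the trait
#'   scale (default `TRUE` adds it; BLUP deviations otherwise)
#' @param blocks optional accession -> subpopulation map for a random block
#' @return numeric matrix (accessions x traits) with attribute `transform`
#' @export
trait_matrix <- function(records, traits = NULL, method = c("blup", "lsmean"),
                         transform = NULL, center_blups = TRUE, blocks = NULL) {
  method <- match.arg(method)
  traits <- traits %||% unique(records$trait)
  if (anyDuplicated(traits)) stopf("duplicated trait names")
  transform <- transform %||% attr(records, "transform") %||%
    stats::setNames(rep("identity", length(traits)), traits)
  acc <- sort(unique(records$accession))
  out <- matrix(NA_real_, length(acc), length(traits),
                dimnames = list(acc, traits))
  tags <- stats::setNames(rep("identity", length(traits)), traits)
  for (t in traits) {
    lt <- isTRUE(transform[t] %in% c("exp", "log"))
    if (lt) tags[t] <- "log"
    if (method == "blup") {
      f <- fit_two_level_reml(records, t, blocks = blocks, log_transform = lt)
      v <- f$blups + if (center_blups) f$grand_mean else 0
    } else {
      v <- lsmeans(records, t, log_transform = lt)
    }
    out[names(v), t] <- v
  }
  attr(out, "transform") <- tags
  attr(out, "method") <- method
  out
}

#' Trait-trait Pearson correlation matrix with p-values
#' @param tm trait matrix from [trait_matrix()]
#' @return list of matrices `r` and `p` (symmetric, unit diagonal on `r`)
#' @export
correlation_matrix <- function(tm) {
  k <- ncol(tm)
  r <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- list(colnames(tm), colnames(tm))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ct <- pearson_with_t(tm[, i], tm[, j])
    r[i, j] <- r[j, i] <- ct$r
    p[i, j] <- p[j, i] <- ct$p
  }
  list(r = r, p = p)
}
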