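# Gaussian Bayesian network learning over the accession x trait matrix:
# HITON-PC Markov-blanket screening by partial-correlation t-tests,
# score-based hill climbing maximising the Gaussian BIC under growth-stage
# blacklists, and 10-fold cross-validated model selection.

#' Partial correlation with Student's t-test
#'
#' Correlation of `x` and `y` given conditioning set `Z`, computed from the
#' residuals of least-squares regressions on `Z`; tested with
#' `t = r sqrt((n - |Z| - 2) / (1 - r^2))` on `n - |Z| - 2` df. An empty `Z`
#' reduces to [pearson_with_t()].
#'
#' @param data numeric matrix (rows = accessions, columns = traits)
#' @param x,y column names or indices
#' @param z character/integer vector of conditioning columns (may be empty)
#' @return list with `r`, `p`, `n`, `df`
#' @export
partial_corr_test <- function(data, x, y, z = character(0)) {
  d <- data[stats::complete.cases(data[, c(x, y, z), drop = FALSE]), ,
            drop = FALSE]
  n <- nrow(d)
  if (n <= length(z) + 2) stopf("need n > |Z| + 2 observations")
  xv <- d[, x]; yv <- d[, y]
  if (length(z)) {
    Zm <- cbind(1, d[, z, drop = FALSE])
    qz <- qr(Zm)
    if (qz$rank < ncol(Zm)) {
      warnf("singular conditioning block; dropping collinear columns")
      Zm <- Zm[, qz$pivot[seq_len(qz$rank)], drop = FALSE]
      qz <- qr(Zm)
    }
    xv <- qr.resid(qz, xv)
    yv <- qr.resid(qz, yv)
  }
  sx <- sqrt(sum((xv - mean(xv))^2)); sy <- sqrt(sum((yv - mean(yv))^2))
  if (sx == 0 || sy == 0) {
    warnf("zero-variance residual in partial correlation")
    return(list(r = NA_real_, p = NA_real_, n = n, df = n - length(z) - 2))
  }
  r <- sum((xv - mean(xv)) * (yv - mean(yv))) / (sx * sy)
  r <- max(-1, min(1, r))
  df <- n - length(z) - 2
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n, df = df))
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(tt), df, lower.tail = FALSE), n = n,
       df = df)
}

#' Parent/children candidate set by semi-interleaved HITON-PC
#'
#' Candidates are ranked by unconditional association with the target and
#' admitted in turn; a candidate is rejected (permanently) if any subset of
#' the current set, up to `max_cond`, renders it independent of the target at
#' level `alpha`. After each admission the existing members are re-checked
#' the same way.
#'
#' @param data numeric trait matrix
#' @param target target trait (column name)
#' @param alpha screening significance level (default 0.1)
#' @param max_cond maximum conditioning-set size (default 3)
#' @return character vector of retained traits (possibly empty)
#' @export
hiton_pc <- function(data, target, alpha = 0.1, max_cond = 3) {
  vars <- setdiff(colnames(data), target)
  dup <- vars[vapply(vars, function(v)
    isTRUE(all.equal(unname(data[, v]), unname(data[, target]))), TRUE)]
  if (length(dup))
    warnf("variable(s) duplicating the target flagged degenerate: %s",
          paste(dup, collapse = ", "))
  assoc <- vapply(vars, function(v) {
    ct <- pearson_with_t(data[, target], data[, v])
    if (is.na(ct$p) || ct$p >= alpha) NA_real_ else abs(ct$r)
  }, 0)
  open <- vars[!is.na(assoc)]
  open <- open[order(-assoc[open])]
  pc <- character(0)
  sep_ok <- function(v, set) {
    # TRUE if some conditioning subset of `set` separates v from target
    for (k in seq_len(min(length(set), max_cond))) {
      combs <- utils::combn(set, k, simplify = FALSE)
      for (S in combs) {
        ct <- partial_corr_test(data, target, v, S)
        if (is.na(ct$p) || ct$p >= alpha) return(TRUE)
      }
    }
    FALSE
  }
  for (v in open) {
    if (length(pc) && sep_ok(v, pc)) next
    pc <- c(pc, v)
    # interleaved elimination of existing members
    drop <- character(0)
    for (w in pc) {
      others <- setdiff(pc, w)
      if (length(others) && sep_ok(w, others)) drop <- c(drop, w)
    }
    pc <- setdiff(pc, drop)
  }
  pc
}

#' Growth-stage blacklist
#'
#' Forbids every arc from a later developmental stage to a strictly earlier
#' one; arcs within a stage stay unrestricted (so two traits staged together
#' can relate in either direction).
#'
#' @param stages named integer (or ordered) vector trait -> stage index
#' @return data.frame of class `bn_blacklist` with columns from, to, reason
#' @export
stage_blacklist <- function(stages) {
  if (is.null(names(stages))) stopf("stages must be a named vector")
  traits <- names(stages)
  from <- character(0); to <- character(0)
  for (a in traits) for (b in traits) {
    if (a != b && stages[a] > stages[b]) {
      from <- c(from, a); to <- c(to, b)
    }
  }
  structure(data.frame(from = from, to = to, reason = "stage order",
                       stringsAsFactors = FALSE),
            class = c("bn_blacklist", "data.frame"))
}

#' Default trait staging for the arsenic-related trait system
#'
#' Flowering and height first, grain element concentrations second,
#' straighthead severity last.
#' @param traits trait names present in the data
#' @return named stage vector suitable for [stage_blacklist()]
#' @export
default_stages <- function(traits = c("DHDnt", "PHTnt", "Si", "As", "P", "S",
                                      "Ca", "Cu", "StHDms")) {
  stage <- ifelse(traits %in% c("DHDnt", "PHTnt"), 1L,
                  ifelse(traits %in% c("StHDms", "StHD"), 3L, 2L))
  stats::setNames(stage, traits)
}

# Gaussian BIC of one node given parents (larger is better): maximum
# likelihood linear regression with parameters = |parents| + intercept +
# variance.
node_bic <- function(data, node, parents, n = nrow(data)) {
  y <- data[, node]
  X <- cbind(1, data[, parents, drop = FALSE])
  res <- qr.resid(qr(X), y)
  s2 <- sum(res^2) / n
  ll <- -0.5 * n * (log(2 * pi * s2) + 1)
  ll - 0.5 * log(n) * (length(parents) + 2)
}

# total BIC of a DAG given as a named list of parent vectors
dag_bic <- function(data, parents) {
  sum(vapply(names(parents), function(v) node_bic(data, v, parents[[v]]), 0))
}

# does adding arc from->to create a cycle? (DFS from `to` looking for `from`)
creates_cycle <- function(parents, from, to) {
  children <- function(v) names(parents)[vapply(parents, function(p) v %in% p, TRUE)]
  stack <- to; seen <- character(0)
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    if (v == from) return(TRUE)
    if (v %in% seen) next
    seen <- c(seen, v)
    stack <- c(stack, children(v))
  }
  FALSE
}

#' Score-based DAG search by greedy hill climbing
#'
#' Starts from the empty graph and repeatedly applies the single-arc
#' addition, deletion or reversal that most increases the Gaussian BIC
#' (larger is better), subject to the blacklist, an optional candidate-set
#' restriction, and acyclicity, until no move improves the score.
#'
#' @param data numeric trait matrix; rows with missing values are dropped
#'   (count reported via message)
#' @param blacklist data.frame with columns from, to (or `NULL`)
#' @param restrict optional named list trait -> candidate neighbour set (from
#'   [hiton_pc()]); an arc u -> v is allowed when u is a candidate of v or v
#'   of u
#' @param max_parents cap on parents per node (default `Inf`)
#' @return object of class `trait_dag`: nodes, `arcs` data.frame (from, to,
#'   coef), `parents` list, `score` (BIC), `n_used`
#' @export
hill_climb <- function(data, blacklist = NULL, restrict = NULL,
                       max_parents = Inf) {
  cc <- stats::complete.cases(data)
  if (any(!cc)) message(sprintf("dropping %d rows with missing trait values",
                                sum(!cc)))
  data <- data[cc, , drop = FALSE]
  nodes <- colnames(data)
  banned <- function(u, v) {
    if (!is.null(blacklist) && nrow(blacklist) &&
        any(blacklist$from == u & blacklist$to == v)) return(TRUE)
    if (!is.null(restrict) &&
        !(u %in% (restrict[[v]] %||% character(0)) ||
          v %in% (restrict[[u]] %||% character(0)))) return(TRUE)
    FALSE
  }
  parents <- stats::setNames(lapply(nodes, function(.) character(0)), nodes)
  node_scores <- vapply(nodes, function(v) node_bic(data, v, parents[[v]]), 0)
  repeat {
    best <- NULL; best_gain <- 1e-9
    for (u in nodes) for (v in nodes) {
      if (u == v) next
      has <- u %in% parents[[v]]
      if (!has && !banned(u, v) && length(parents[[v]]) < max_parents &&
          !creates_cycle(parents, u, v)) {
        gain <- node_bic(data, v, c(parents[[v]], u)) - node_scores[v]
        if (gain > best_gain) { best_gain <- gain; best <- list("add", u, v) }
      }
      if (has) {
        gain <- node_bic(data, v, setdiff(parents[[v]], u)) - node_scores[v]
        if (gain > best_gain) { best_gain <- gain; best <- list("del", u, v) }
        # reversal u->v to v->u
        if (!banned(v, u) && length(parents[[u]]) < max_parents) {
          p2 <- parents; p2[[v]] <- setdiff(p2[[v]], u)
          if (!creates_cycle(p2, v, u)) {
            gain <- (node_bic(data, v, setdiff(parents[[v]], u)) - node_scores[v]) +
              (node_bic(data, u, c(parents[[u]], v)) - node_scores[u])
            if (gain > best_gain) { best_gain <- gain; best <- list("rev", u, v) }
          }
        }
      }
    }
    if (is.null(best)) break
    u <- best[[2]]; v <- best[[3]]
    if (best[[1]] == "add") parents[[v]] <- c(parents[[v]], u)
    if (best[[1]] == "del") parents[[v]] <- setdiff(parents[[v]], u)
    if (best[[1]] == "rev") {
      parents[[v]] <- setdiff(parents[[v]], u)
      parents[[u]] <- c(parents[[u]], v)
    }
    node_scores[v] <- node_bic(data, v, parents[[v]])
    node_scores[u] <- node_bic(data, u, parents[[u]])
  }
  arcs <- do.call(rbind, lapply(nodes, function(v) {
    if (!length(parents[[v]])) return(NULL)
    cf <- stats::lm.fit(cbind(1, data[, parents[[v]], drop = FALSE]),
                        data[, v])$coefficients[-1]
    data.frame(from = parents[[v]], to = v, coef = as.numeric(cf),
               stringsAsFactors = FALSE)
  }))
  if (is.null(arcs)) arcs <- data.frame(from = character(), to = character(),
                                        coef = numeric())
  structure(list(nodes = nodes, arcs = arcs, parents = parents,
                 score = sum(node_scores), n_used = nrow(data)),
            class = "trait_dag")
}

#' @export
print.trait_dag <- function(x, ...) {
  cat(sprintf("trait_dag: %d nodes, %d arcs, BIC %.2f\n",
              length(x$nodes), nrow(x$arcs), x$score))
  if (nrow(x$arcs))
    for (i in seq_len(nrow(x$arcs)))
      cat(sprintf("  %s -> %s (coef %.3f%s)\n", x$arcs$from[i], x$arcs$to[i],
                  x$arcs$coef[i],
                  if (!is.null(x$arcs$strength))
                    sprintf(", strength %.2f", x$arcs$strength[i]) else ""))
  invisible(x)
}

#' Verify a DAG is acyclic (topological sort)
#' @param dag a `trait_dag`
#' @return `TRUE` (invisibly) or an error
#' @export
check_acyclic <- function(dag) {
  if (is.null(topo_order_arcs(dag$nodes, dag$arcs)))
    stopf("graph contains a cycle")
  invisible(TRUE)
}

#' Bayesian network configuration
#' @param alpha HITON-PC screening level (default 0.1)
#' @param folds cross-validation folds (default 10)
#' @param validation_size accessions per validation set (default 17)
#' @param seed integer seed
#' @return object of class `bn_config`
#' @export
bn_config <- function(alpha = 0.1, folds = 10, validation_size = 17,
                      seed = 1) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  structure(list(alpha = alpha, folds = folds,
                 validation_size = validation_size, seed = as.integer(seed),
                 score = "gaussian BIC"), class = "bn_config")
}

#' Cross-validated network learning
#'
#' For each fold, a random validation set of `validation_size` accessions is
#' held out, HITON-PC candidate sets and a hill-climbed DAG are learned on
#' the training split, and the held-out Gaussian log-likelihood is recorded.
#' Arc strength is the fraction of folds whose DAG contains the arc. The
#' final model is, by default, the fold DAG whose BIC recomputed on the full
#' data is maximal (`combine = "select"`); `combine = "average"` instead
#' keeps arcs with strength at least 0.5 (majority vote) and refits their
#' coefficients on the full data.
#'
#' @param data numeric trait matrix
#' @param config a [bn_config()]
#' @param blacklist arc blacklist (data.frame from, to) or `NULL`
#' @param combine `"select"` (default) or `"average"`
#' @return `trait_dag` with per-arc `strength`, plus attributes
#'   `fold_loglik` (held-out log-likelihoods) and `strengths` (all arcs seen)
#' @export
cv_learn <- function(data, config = bn_config(), blacklist = NULL,
                     combine = c("select", "average")) {
  combine <- match.arg(combine)
  stopifnot(inherits(config, "bn_config"))
  data <- data[stats::complete.cases(data), , drop = FALSE]
  n <- nrow(data)
  if (n < config$folds) stopf("need at least as many accessions as folds")
  if (config$validation_size >= n) stopf("validation_size must be < n")
  set.seed(config$seed)
  fold_dags <- vector("list", config$folds)
  fold_ll <- numeric(config$folds)
  arc_keys <- character(0)
  for (f in seq_len(config$folds)) {
    vs <- sample.int(n, config$validation_size)
    train <- data[-vs, , drop = FALSE]
    valid <- data[vs, , drop = FALSE]
    zerovar <- apply(train, 2, stats::sd) == 0
    if (any(zerovar)) {
      warnf("fold %d skipped: zero-variance trait(s) %s", f,
            paste(colnames(train)[zerovar], collapse = ", "))
      fold_ll[f] <- NA_real_
      next
    }
    restrict <- lapply(stats::setNames(colnames(train), colnames(train)),
                       function(t) hiton_pc(train, t, alpha = config$alpha))
    dag <- hill_climb(train, blacklist = blacklist, restrict = restrict)
    fold_dags[[f]] <- dag
    fold_ll[f] <- gaussian_loglik(dag, train, valid)
    if (nrow(dag$arcs))
      arc_keys <- c(arc_keys, paste(dag$arcs$from, dag$arcs$to, sep = "->"))
  }
  kept <- !vapply(fold_dags, is.null, TRUE)
  if (!any(kept)) stopf("all folds failed")
  strengths <- table(arc_keys) / sum(kept)
  # final model
  if (combine == "select") {
    full_bic <- vapply(fold_dags[kept], function(d) dag_bic(data, d$parents), 0)
    final <- fold_dags[kept][[which.max(full_bic)]]
    # refit coefficients and score on the full data
    final <- refit_dag(final, data)
  } else {
    keep_arcs <- names(strengths)[strengths >= 0.5]
    parents <- stats::setNames(lapply(colnames(data), function(.) character(0)),
                               colnames(data))
    for (k in keep_arcs) {
      uv <- strsplit(k, "->", fixed = TRUE)[[1]]
      if (!creates_cycle(parents, uv[1], uv[2]))
        parents[[uv[2]]] <- c(parents[[uv[2]]], uv[1])
    }
    final <- refit_dag(structure(list(nodes = colnames(data),
                                      parents = parents), class = "trait_dag"),
                       data)
  }
  key <- paste(final$arcs$from, final$arcs$to, sep = "->")
  final$arcs$strength <- as.numeric(strengths[key])
  final$arcs$strength[is.na(final$arcs$strength)] <- 1 / sum(kept)
  attr(final, "fold_loglik") <- fold_ll
  attr(final, "strengths") <- strengths
  check_acyclic(final)
  if (!is.null(blacklist) && nrow(blacklist) && nrow(final$arcs)) {
    bad <- paste(final$arcs$from, final$arcs$to) %in%
      paste(blacklist$from, blacklist$to)
    if (any(bad)) stopf("internal error: blacklisted arc in output")
  }
  final
}

# refit arc coefficients and BIC of a DAG skeleton on (full) data
refit_dag <- function(dag, data) {
  nodes <- colnames(data)
  parents <- dag$parents
  arcs <- do.call(rbind, lapply(nodes, function(v) {
    if (!length(parents[[v]])) return(NULL)
    cf <- stats::lm.fit(cbind(1, data[, parents[[v]], drop = FALSE]),
                        data[, v])$coefficients[-1]
    data.frame(from = parents[[v]], to = v, coef = as.numeric(cf),
               stringsAsFactors = FALSE)
  }))
  if (is.null(arcs)) arcs <- data.frame(from = character(), to = character(),
                                        coef = numeric())
  structure(list(nodes = nodes, arcs = arcs, parents = parents,
                 score = dag_bic(data, parents), n_used = nrow(data)),
            class = "trait_dag")
}

# held-out Gaussian log-likelihood of `valid` under node regressions fit on
# `train`
gaussian_loglik <- function(dag, train, valid) {
  ll <- 0
  for (v in dag$nodes) {
    pa <- dag$parents[[v]]
    Xt <- cbind(1, train[, pa, drop = FALSE])
    cf <- stats::lm.fit(Xt, train[, v])$coefficients
    s2 <- sum(qr.resid(qr(Xt), train[, v])^2) / nrow(train)
    Xv <- cbind(1, valid[, pa, drop = FALSE])
    mu <- drop(Xv %*% cf)
    ll <- ll + sum(stats::dnorm(valid[, v], mu, sqrt(s2), log = TRUE))
  }
  ll
}
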