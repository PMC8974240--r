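# Synthetic structured inbred panel: Balding-Nichols subpopulation drift,
# planted QTL, and a known trait causal graph, so every downstream stage can
# be tested with planted truth instead of downloaded data.

#' Configuration for a synthetic diversity panel
#'
#' Describes a structured panel of homozygous inbred accessions: subpopulation
#' sizes (an `ADMIX` entry is treated as 50/50 mixtures of two parent
#' subpopulations), chromosome map, marker count, and the Balding-Nichols
#' divergence parameter `fst` that controls how far subpopulation allele
#' frequencies drift from the ancestral frequency.
#'
#' Defaults emulate the USDA rice minicore: 167 accessions in five named
#' subpopulations plus admixed, 12 chromosomes with rice-like lengths.
#'
#' @param n_accessions total number of accessions
#' @param subpop_sizes named integer vector of subpopulation sizes; a member
#'   named `ADMIX` designates admixed accessions
#' @param n_chromosomes number of chromosomes
#' @param chrom_lengths chromosome lengths in bp (recycled/validated against
#'   `n_chromosomes`); defaults to rice-like lengths
#' @param n_snps total marker count, allocated to chromosomes by length
#' @param fst divergence parameter in `[0, 1)`; 0 is the no-drift limit
#' @param ancestral_maf_range range `(lo, hi)` in `(0, 0.5]` for ancestral
#'   allele frequencies (drawn uniformly)
#' @param inbred logical; if `TRUE` (default) dosages are in `{0, 2}` only
#' @param missing_rate per-entry missing genotype probability (default 0)
#' @param ld_block_size markers per linkage block; 1 (default) gives
#'   independent markers, larger values make consecutive markers correlated
#' @param ld_switch_prob per-accession probability that a marker within a
#'   block is redrawn independently of the block founder
#' @param seed integer seed; identical seeds give bit-identical panels
#' @return an object of class `panel_config`
#' @export
panel_config <- function(n_accessions = 167,
                         subpop_sizes = c(AUS = 30, IND = 54, TEJ = 29,
                                          TRJ = 28, ARO = 6, ADMIX = 20),
                         n_chromosomes = 12,
                         chrom_lengths = NULL,
                         n_snps = 10000,
                         fst = 0.1,
                         ancestral_maf_range = c(0.05, 0.5),
                         inbred = TRUE,
                         missing_rate = 0,
                         ld_block_size = 1,
                         ld_switch_prob = 0.1,
                         seed = 1) {
  if (is.null(chrom_lengths)) {
    rice <- c(43.3, 35.9, 36.4, 35.5, 29.9, 31.2,
              29.7, 28.4, 23.0, 23.2, 29.0, 27.5) * 1e6
    chrom_lengths <- if (n_chromosomes <= 12) rice[seq_len(n_chromosomes)] else
      rep_len(rice, n_chromosomes)
  }
  if (length(chrom_lengths) != n_chromosomes)
    stopf("chrom_lengths has %d entries for %d chromosomes",
          length(chrom_lengths), n_chromosomes)
  if (any(chrom_lengths <= 0)) stopf("zero-length chromosome in config")
  if (sum(subpop_sizes) != n_accessions)
    stopf("subpopulation sizes sum to %d, not n_accessions = %d",
          sum(subpop_sizes), n_accessions)
  if (fst < 0 || fst >= 1) stopf("fst must lie in [0, 1), got %g", fst)
  lo <- ancestral_maf_range[1]; hi <- ancestral_maf_range[2]
  if (lo <= 0 || hi > 0.5 || lo > hi)
    stopf("ancestral_maf_range must satisfy 0 < lo <= hi <= 0.5")
  if (ld_block_size < 1) stopf("ld_block_size must be >= 1")
  cfg <- list(n_accessions = n_accessions, subpop_sizes = subpop_sizes,
              n_chromosomes = n_chromosomes, chrom_lengths = chrom_lengths,
              n_snps = n_snps, fst = fst,
              ancestral_maf_range = c(lo, hi), inbred = inbred,
              missing_rate = missing_rate, ld_block_size = ld_block_size,
              ld_switch_prob = ld_switch_prob, seed = as.integer(seed))
  class(cfg) <- "panel_config"
  cfg
}

#' Simulate structured inbred-panel genotypes
#'
#' Draws ancestral allele frequencies uniformly on the configured range, then
#' per-subpopulation frequencies from the Balding-Nichols Beta distribution
#' `Beta(p(1-fst)/fst, (1-p)(1-fst)/fst)` (the `fst = 0` limit uses the
#' ancestral frequency directly). Admixed accessions use 50/50 mixtures of two
#' parent subpopulation frequency vectors. Inbred dosages are `2 *
#' Bernoulli(f)` so heterozygotes never occur.
#'
#' @param config a [panel_config()]
#' @return an object of class `genotype_matrix` with elements `dosages`
#'   (accession x SNP integer matrix in `{0, 2}`, `NA` = missing), `map`
#'   (data.frame: snp, chr, pos, ref, alt), `subpop` (labels), `inbred`
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(config$seed)
  n <- config$n_accessions
  m <- config$n_snps
  sizes <- config$subpop_sizes
  pops <- names(sizes) %||% paste0("POP", seq_along(sizes))
  subpop <- rep(pops, sizes)
  acc <- sprintf("ACC%03d", seq_len(n))

  # marker map: counts per chromosome proportional to length, positions
  # strictly increasing
  wl <- config$chrom_lengths / sum(config$chrom_lengths)
  m_chr <- floor(m * wl)
  rem <- m - sum(m_chr)
  if (rem > 0) {
    extra <- order(m * wl - m_chr, decreasing = TRUE)[seq_len(rem)]
    m_chr[extra] <- m_chr[extra] + 1
  }
  chr <- rep(seq_len(config$n_chromosomes), m_chr)
  b <- config$ld_block_size
  pos <- unlist(lapply(seq_len(config$n_chromosomes), function(c) {
    mc <- m_chr[c]
    if (mc == 0) return(integer(0))
    if (b <= 1) return(sort(sample.int(config$chrom_lengths[c], mc)))
    # physically tight linkage blocks: one block per equal chromosome
    # segment, members within a ~100 kb window so the 200 kb chaining rule
    # sees them as one region
    nb <- ceiling(mc / b)
    seg <- config$chrom_lengths[c] / nb
    span <- min(1e5, floor(seg) - b - 1)
    out <- integer(0)
    left <- mc
    for (i in seq_len(nb)) {
      k <- min(b, left); left <- left - k
      start <- floor((i - 1) * seg) + 1 +
        sample.int(max(1, floor(seg - span - 1)), 1)
      out <- c(out, start + sort(sample.int(max(span, k + 1), k)))
    }
    out
  }), use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  snp <- sprintf("S%d_%d", chr, pos)

  lo <- config$ancestral_maf_range[1]; hi <- config$ancestral_maf_range[2]
  p_anc <- stats::runif(m, lo, hi)
  core <- setdiff(pops, "ADMIX")
  # subpopulation frequencies around the ancestral frequency
  f <- matrix(0, nrow = length(core), ncol = m, dimnames = list(core, NULL))
  for (k in core) {
    f[k, ] <- if (config$fst == 0) p_anc else
      stats::rbeta(m, p_anc * (1 - config$fst) / config$fst,
                   (1 - p_anc) * (1 - config$fst) / config$fst)
  }
  # per-accession frequency rows; admixed = 50/50 mix of two parents
  freq <- matrix(0, nrow = n, ncol = m)
  admix_parents <- character(0)
  for (i in seq_len(n)) {
    if (subpop[i] == "ADMIX") {
      par <- sample(core, 2)
      admix_parents[length(admix_parents) + 1] <- paste(par, collapse = "/")
      freq[i, ] <- (f[par[1], ] + f[par[2], ]) / 2
    } else {
      freq[i, ] <- f[subpop[i], ]
    }
  }

  b <- config$ld_block_size
  if (!config$inbred) {
    # two independent allele draws per accession; LD blocks not supported here
    dos <- matrix(stats::rbinom(n * m, 2L, as.vector(freq)), nrow = n)
  } else if (b <= 1) {
    dos <- matrix(stats::rbinom(n * m, 1L, as.vector(freq)) * 2L, nrow = n)
  } else {
    # linkage blocks: markers copy a per-accession block founder allele,
    # redrawn independently with probability ld_switch_prob
    dos <- matrix(0L, nrow = n, ncol = m)
    within_idx <- unlist(lapply(m_chr, seq_len), use.names = FALSE)
    block <- split(seq_len(m),
                   interaction(chr, (within_idx - 1) %/% b, drop = TRUE))
    for (idx in block) {
      z <- stats::rbinom(n, 1L, freq[, idx[1]])
      for (j in idx) {
        keep <- stats::rbinom(n, 1L, 1 - config$ld_switch_prob)
        fresh <- stats::rbinom(n, 1L, freq[, j])
        dos[, j] <- (keep * z + (1L - keep) * fresh) * 2L
      }
    }
  }
  if (config$missing_rate > 0) {
    miss <- stats::runif(n * m) < config$missing_rate
    dos[miss] <- NA_integer_
  }
  dimnames(dos) <- list(acc, snp)

  structure(list(
    dosages = dos,
    map = data.frame(snp = snp, chr = chr, pos = pos, ref = ref, alt = alt,
                     stringsAsFactors = FALSE),
    subpop = stats::setNames(subpop, acc),
    admix_parents = admix_parents,
    inbred = config$inbred
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d SNPs on %d chromosomes%s\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chr)),
              if (x$inbred) " (inbred)" else ""))
  invisible(x)
}

#' Planted truth for trait simulation
#'
#' Collects the planted QTL, the directed trait graph, and the variance
#' parameters that define the simulated world. Traits are generated on a
#' latent scale; traits tagged `transform = "exp"` are exponentiated so raw
#' records are right-skewed (log-transform recovers the latent scale), and a
#' trait with `bounds` is clamped (e.g. a 0-9 severity score).
#'
#' @param traits character vector of trait names
#' @param qtl data.frame with columns `trait`, `chr`, `pos`, `effect`
#'   (per-allele-copy effect in latent trait units); may be empty
#' @param arcs data.frame with columns `from`, `to`, `coef` (path coefficient
#'   applied to the parent's centered accession value); must be acyclic
#' @param intercept,polygenic_sd,env_sd,noise_sd named numeric vectors per
#'   trait (recycled from scalars)
#' @param transform named character vector per trait, `"identity"` or `"exp"`
#' @param bounds named list of `c(lo, hi)` latent clamps (applied after
#'   env/rep noise), e.g. `list(StHDms = c(0, 9))`
#' @return object of class `truth_set`
#' @export
truth_set <- function(traits, qtl = NULL, arcs = NULL,
                      intercept = 0, polygenic_sd = 1, env_sd = 0.25,
                      noise_sd = 0.5, transform = "identity", bounds = list()) {
  fill <- function(x, default) {
    out <- stats::setNames(rep_len(default, length(traits)), traits)
    if (!is.null(names(x))) out[names(x)] <- x else out[] <- rep_len(x, length(traits))
    out
  }
  qtl <- qtl %||% data.frame(trait = character(), chr = integer(),
                             pos = integer(), effect = numeric())
  arcs <- arcs %||% data.frame(from = character(), to = character(),
                               coef = numeric())
  if (nrow(arcs) && is.null(topo_order_arcs(traits, arcs)))
    stopf("truth arcs contain a cycle")
  if (!all(qtl$trait %in% traits)) stopf("planted QTL names unknown trait")
  tr <- structure(list(
    traits = traits, qtl = qtl, arcs = arcs,
    intercept = fill(intercept, 0), polygenic_sd = fill(polygenic_sd, 1),
    env_sd = fill(env_sd, 0.25), noise_sd = fill(noise_sd, 0.5),
    transform = fill(transform, "identity"), bounds = bounds
  ), class = "truth_set")
  bad <- setdiff(tr$transform, c("identity", "exp"))
  if (length(bad)) stopf("unknown transform: %s", paste(bad, collapse = ", "))
  tr
}

# Kahn topological order of traits under arcs; NULL if cyclic.
topo_order_arcs <- function(traits, arcs) {
  indeg <- stats::setNames(integer(length(traits)), traits)
  for (t in arcs$to) indeg[t] <- indeg[t] + 1L
  order <- character(0)
  avail <- names(indeg)[indeg == 0L]
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]
    order <- c(order, v)
    kids <- arcs$to[arcs$from == v]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) avail <- c(avail, k)
    }
  }
  if (length(order) == length(traits)) order else NULL
}

#' Default nine-trait truth emulating an arsenic-related trait system
#'
#' Developmental stages: flowering (DHDnt) and height (PHTnt) upstream, grain
#' element concentrations (Si, As, P, S, Ca, Cu) intermediate, straighthead
#' severity (StHDms) terminal. Arc coefficients are moderate-to-strong
#' (|coef| >= 0.4) so that structure learning has signal at a 167-accession
#' panel size; element traits are exponentiated (right-skewed raw scale) and
#' StHDms is clamped to the 0-9 rating scale.
#'
#' @param genotypes optional `genotype_matrix`; when given, pleiotropic QTL
#'   are planted at real marker positions (the marker with alternate-allele
#'   frequency nearest 0.3 on chromosomes 1, 6 and 8)
#' @return a [truth_set()]
#' @export
default_truth <- function(genotypes = NULL) {
  traits <- c("DHDnt", "PHTnt", "Si", "As", "P", "S", "Ca", "Cu", "StHDms")
  arcs <- data.frame(
    from = c("DHDnt", "DHDnt", "DHDnt", "PHTnt", "As", "As", "Cu"),
    to   = c("PHTnt", "As",    "Cu",    "StHDms", "P", "StHDms", "StHDms"),
    coef = c(0.8,     0.45,    -0.5,    0.5,      0.45, 0.4,     -0.4))
  qtl <- NULL
  if (!is.null(genotypes)) {
    pick <- function(c) {
      # marker with alt frequency nearest 0.3, so planted QTL are detectable
      i <- which(genotypes$map$chr == c)
      f <- colMeans(genotypes$dosages[, i, drop = FALSE], na.rm = TRUE) / 2
      genotypes$map[i[which.min(abs(f - 0.3))], c("chr", "pos")]
    }
    p1 <- pick(1); p6 <- pick(6); p8 <- pick(8)
    qtl <- data.frame(
      trait = c("Si", "As", "StHDms", "DHDnt"),
      chr = c(p6$chr, p8$chr, p8$chr, p1$chr),
      pos = c(p6$pos, p8$pos, p8$pos, p1$pos),
      effect = c(0.6, 0.5, 0.5, 0.5))
  }
  truth_set(
    traits, qtl = qtl, arcs = arcs,
    intercept = c(DHDnt = 90, PHTnt = 110, Si = log(200), As = log(0.25),
                  P = log(2800), S = log(900), Ca = log(90), Cu = log(3),
                  StHDms = 6),
    polygenic_sd = c(DHDnt = 1, PHTnt = 1, Si = 0.4, As = 0.4, P = 0.3,
                     S = 0.3, Ca = 0.35, Cu = 0.4, StHDms = 1),
    env_sd = 0.2, noise_sd = 0.3,
    transform = c(Si = "exp", As = "exp", P = "exp", S = "exp",
                  Ca = "exp", Cu = "exp"),
    bounds = list(StHDms = c(0, 9)))
}

#' Simulate replicated phenotypes from genotypes and a truth set
#'
#' Each trait's accession-level latent value is `intercept + sum(planted QTL
#' effect x dosage) + sum(arc coef x centered parent value) + polygenic
#' N(0, polygenic_sd^2)`. Records add a per-environment effect `N(0, env_sd^2)`
#' and replicate noise `N(0, noise_sd^2)`, then apply bounds clamps and the
#' `exp` transform for skewed element traits.
#'
#' @param genotypes a `genotype_matrix`
#' @param truth a [truth_set()]; planted QTL positions must exist on the map
#' @param n_env,n_rep numbers of environments and replicates (defaults 2 x 2)
#' @param seed integer seed for the phenotype noise streams
#' @return a long-format data.frame of class `replicated_phenotypes` with
#'   columns accession, env, rep, trait, value; truth accession values kept in
#'   `attr(, "accession_values")`
#' @export
simulate_traits <- function(genotypes, truth, n_env = 2, n_rep = 2, seed = 1) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(truth, "truth_set"))
  set.seed(seed)
  n <- nrow(genotypes$dosages)
  acc <- rownames(genotypes$dosages)
  ord <- topo_order_arcs(truth$traits, truth$arcs)
  if (is.null(ord)) stopf("truth arcs contain a cycle")

  # resolve planted QTL to marker columns
  qtl <- truth$qtl
  qcol <- integer(nrow(qtl))
  for (i in seq_len(nrow(qtl))) {
    j <- which(genotypes$map$chr == qtl$chr[i] & genotypes$map$pos == qtl$pos[i])
    if (!length(j))
      stopf("planted QTL for %s at chr%s:%d is not on the marker map",
            qtl$trait[i], qtl$chr[i], qtl$pos[i])
    qcol[i] <- j[1]
  }

  vals <- matrix(0, nrow = n, ncol = length(truth$traits),
                 dimnames = list(acc, truth$traits))
  for (t in ord) {
    g <- rep(0, n)
    for (i in which(qtl$trait == t)) {
      d <- genotypes$dosages[, qcol[i]]
      d[is.na(d)] <- mean(d, na.rm = TRUE)
      g <- g + qtl$effect[i] * d
    }
    up <- rep(0, n)
    for (i in which(truth$arcs$to == t)) {
      pv <- vals[, truth$arcs$from[i]]
      up <- up + truth$arcs$coef[i] * (pv - mean(pv))
    }
    vals[, t] <- truth$intercept[t] + g + up +
      stats::rnorm(n, 0, truth$polygenic_sd[t])
  }

  recs <- expand.grid(accession = acc, env = sprintf("E%d", seq_len(n_env)),
                      rep = seq_len(n_rep), trait = truth$traits,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  env_eff <- matrix(stats::rnorm(n_env * length(truth$traits), 0,
                                 rep(truth$env_sd, each = n_env)),
                    nrow = n_env, dimnames = list(NULL, truth$traits))
  v <- vals[cbind(recs$accession, recs$trait)] +
    env_eff[cbind(match(recs$env, sprintf("E%d", seq_len(n_env))),
                  match(recs$trait, truth$traits))] +
    stats::rnorm(nrow(recs), 0, truth$noise_sd[recs$trait])
  for (t in names(truth$bounds)) {
    i <- recs$trait == t
    v[i] <- pmin(pmax(v[i], truth$bounds[[t]][1]), truth$bounds[[t]][2])
  }
  ex <- truth$transform[recs$trait] == "exp"
  v[ex] <- exp(v[ex])
  recs$value <- v
  attr(recs, "accession_values") <- vals
  attr(recs, "transform") <- truth$transform
  class(recs) <- c("replicated_phenotypes", "data.frame")
  recs
}

#' Write a truth set to JSON (lossless round trip)
#' @param truth a [truth_set()]
#' @param path output file path
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_set"))
  jsonlite::write_json(unclass(truth), path, digits = NA, auto_unbox = FALSE,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read a truth set written by [write_truth()]
#' @param path JSON file path
#' @return a [truth_set()]
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  qtl <- as.data.frame(x$qtl, stringsAsFactors = FALSE)
  arcs <- as.data.frame(x$arcs, stringsAsFactors = FALSE)
  if (!nrow(qtl)) qtl <- NULL
  if (!nrow(arcs)) arcs <- NULL
  truth_set(x$traits, qtl = qtl, arcs = arcs,
            intercept = unlist(x$intercept), polygenic_sd = unlist(x$polygenic_sd),
            env_sd = unlist(x$env_sd), noise_sd = unlist(x$noise_sd),
            transform = unlist(x$transform),
            bounds = lapply(x$bounds, unlist))
}
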