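# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# assoc_records data.frame from bare vectors, defaulting the allele metadata
make_assoc <- function(pos, minus_log10_p, chr = 1, effect = 1,
                       n_common = 100, n_alt = 30, trait = "T",
                       panel = "All", common = "A", alt = "G") {
  k <- length(pos)
  out <- data.frame(
    snp = sprintf("S%d_%d", rep_len(chr, k), pos),
    chr = rep_len(chr, k), pos = pos,
    minus_log10_p = rep_len(minus_log10_p, k),
    effect_common = rep_len(effect, k),
    common_allele = rep_len(common, k), alt_allele = rep_len(alt, k),
    n_common = rep_len(n_common, k), n_alt = rep_len(n_alt, k),
    pct_alt = pct_alt(rep_len(n_common, k), rep_len(n_alt, k)),
    rare_flag = rep_len(n_alt, k) < 6,
    trait = trait, panel = panel, stringsAsFactors = FALSE)
  class(out) <- c("assoc_records", "data.frame")
  out
}

# quadratic-time transitive-closure clustering oracle: two significant SNPs
# share a cluster iff they are connected by a chain of consecutive gaps <=
# extend on the same chromosome
oracle_clusters <- function(assoc, threshold = 5, extend = 200000) {
  sig <- assoc[assoc$minus_log10_p > threshold, , drop = FALSE]
  if (!nrow(sig)) return(list())
  n <- nrow(sig)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- sig$chr[i] == sig$chr[j] &&
      abs(sig$pos[i] - sig$pos[j]) <= extend
  }
  # connected components by breadth-first search over the gap graph
  comp <- rep(NA_integer_, n)
  c <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    c <- c + 1
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- c
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  split(paste(sig$chr, sig$pos), comp)
}

# membership signature of call_clusters output, comparable to the oracle
cluster_signature <- function(clusters) {
  sig <- lapply(clusters, function(c) sort(paste(c$members$chr, c$members$pos)))
  sig[order(vapply(sig, `[`, "", 1))]
}

small_panel <- function(n = 60, n_snps = 400, fst = 0.15, seed = 1, ...) {
  half <- n %/% 2
  simulate_genotypes(panel_config(
    n_accessions = n, subpop_sizes = c(A = half, B = n - half),
    n_snps = n_snps, fst = fst, seed = seed, ...))
}

balanced_records <- function(n = 40, r = 2, sigma_a = 1, sigma_e = 1,
                             mu = 10, seed = 1) {
  set.seed(seed)
  acc <- sprintf("A%03d", seq_len(n))
  a <- stats::rnorm(n, 0, sigma_a)
  d <- expand.grid(accession = acc, env = "E1", rep = seq_len(r),
                   trait = "y", KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$value <- mu + a[match(d$accession, acc)] +
    stats::rnorm(nrow(d), 0, sigma_e)
  class(d) <- c("replicated_phenotypes", "data.frame")
  d
}

# ANOVA-based closed-form REML for the balanced one-way design
anova_oneway <- function(d) {
  ybar <- tapply(d$value, d$accession, mean)
  r <- nrow(d) / length(ybar)
  msb <- r * stats::var(as.numeric(ybar))
  msw <- sum((d$value - ybar[d$accession])^2) /
    (length(ybar) * (r - 1))
  list(s_a = max(0, (msb - msw) / r), s_e = msw, ybar = ybar, r = r)
}

ref_qtl_table <- function() {
  utils::read.delim(system.file("extdata", "rmc_qtl_reference.tsv",
                                package = "panelgwas"),
                    stringsAsFactors = FALSE)
}
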