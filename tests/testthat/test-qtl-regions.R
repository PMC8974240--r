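# Region caller: clustering rules, stringency, merging, sign splits,
# naming, co-location, pivots, gene proximity.

test_that("clustering applies the 200 kb / 50 kb rules", {
  a <- make_assoc(c(1000000, 1150000, 1400000), 6)
  cl <- call_clusters(a)
  expect_length(cl, 2)
  expect_equal(cl[[1]]$snp_span, c(1000000, 1150000))
  expect_equal(cl[[1]]$region, c(950000, 1200000))
  expect_equal(cl[[2]]$snp_span, c(1400000, 1400000))
  expect_equal(cl[[2]]$region, c(1350000, 1450000))
  # boundary clamp at position 1
  cl2 <- call_clusters(make_assoc(30000, 7))
  expect_equal(cl2[[1]]$region, c(1, 80000))
  # sub-threshold records yield nothing
  expect_length(call_clusters(make_assoc(1:3 * 1e6, 4.9)), 0)
})

test_that("greedy chaining equals the transitive-closure oracle", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(1:60, 1)
    a <- make_assoc(sort(sample.int(5e6, n)),
                    stats::runif(n, 3, 8),
                    chr = sample(1:3, n, replace = TRUE))
    got <- cluster_signature(call_clusters(a))
    want <- oracle_clusters(a)
    want <- lapply(want, sort)
    want <- want[order(vapply(want, `[`, "", 1))]
    expect_equal(got, unname(want))
    # every significant SNP lands in exactly one cluster
    all_members <- unlist(got)
    expect_equal(sort(all_members),
                 sort(paste(a$chr, a$pos)[a$minus_log10_p > 5]))
  }
})

test_that("cluster regions within a trait x panel never overlap", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(2:80, 1)
    a <- make_assoc(sort(sample.int(3e6, n)), stats::runif(n, 4, 9))
    cl <- call_clusters(a)
    if (length(cl) < 2) next
    regions <- t(vapply(cl, function(c) c$region, c(0, 0)))
    regions <- regions[order(regions[, 1]), , drop = FALSE]
    expect_true(all(regions[-1, 1] > regions[-nrow(regions), 2]))
  }
})

test_that("stringency flags single-SNP and all-rare clusters", {
  cl1 <- call_clusters(make_assoc(5e5, 7))
  cl1 <- apply_stringency(cl1)
  expect_true(cl1[[1]]$flags["single_snp"])
  expect_false(cl1[[1]]$claimed)

  a <- make_assoc(c(1e6, 1.1e6), 7, n_alt = c(3, 5))
  cl2 <- apply_stringency(call_clusters(a))
  expect_true(cl2[[1]]$flags["all_rare"])
  a3 <- make_assoc(c(1e6, 1.1e6), 7, n_alt = c(3, 8))
  cl3 <- apply_stringency(call_clusters(a3))
  expect_false(cl3[[1]]$flags["all_rare"])
  expect_true(cl3[[1]]$claimed)
})

test_that("cross-panel merging respects the 800 kb gap and sign rules", {
  a <- make_assoc(c(5.0e6, 5.2e6), 6, effect = 10, panel = "A")
  b <- make_assoc(c(5.9e6, 6.0e6), 6, effect = 8, panel = "B")
  one <- merge_panels(call_clusters(rbind(a, b)))
  expect_length(one, 1)
  expect_equal(one[[1]]$start, 4950000)
  expect_equal(one[[1]]$end, 6050000)
  expect_equal(sort(one[[1]]$panels), c("A", "B"))

  b2 <- make_assoc(c(5.9e6, 6.0e6), 6, effect = -8, panel = "B")
  two <- merge_panels(call_clusters(rbind(a, b2)))
  expect_length(two, 2)

  # gap just over 800 kb splits regardless of sign
  c2 <- make_assoc(c(6.01e6, 6.1e6), 6, effect = 10, panel = "A")
  two2 <- merge_panels(c(call_clusters(a), call_clusters(c2)))
  expect_length(two2, 2)
})

test_that("sign flip inside a dense string reproduces the two-QTL pattern", {
  # peaks modelled on the published chr10 pair: positive string peaking at
  # 9,034,052 (+40.40), negative string peaking at 10,773,399 (-32.86),
  # no inter-SNP gap > 800 kb
  pos_str <- make_assoc(c(8900000, 9034052, 9500000), c(5.2, 5.08, 5.5),
                        chr = 10, effect = c(30, 40.40, 25))
  neg_str <- make_assoc(c(9950000, 10500000, 10773399), c(5.3, 5.9, 6.18),
                        chr = 10, effect = c(-20, -28, -32.86))
  qtls <- merge_panels(call_clusters(rbind(pos_str, neg_str),
                                     extend = 800000))
  expect_length(qtls, 2)
  expect_equal(qtls[[1]]$effect_sign, 1)
  expect_equal(qtls[[2]]$effect_sign, -1)
  # regions may overlap: split is at the sign boundary, flanks re-extend
  expect_true(qtls[[1]]$end >= qtls[[2]]$start - 500000)
  nm <- assign_names(qtls, trait_symbol = "Si")
  expect_equal(vapply(nm, function(q) q$name, ""), c("qSi10-1", "qSi10-2"))
})

test_that("merging is invariant to panel input order", {
  a <- make_assoc(c(1e6, 1.2e6), 6, panel = "A")
  b <- make_assoc(c(1.5e6, 1.7e6), 6, panel = "B")
  c_ <- make_assoc(c(3.1e6, 3.2e6), 6, panel = "C")
  q1 <- merge_panels(call_clusters(rbind(a, b, c_)))
  q2 <- merge_panels(c(call_clusters(c_), call_clusters(b),
                       call_clusters(a)))
  key <- function(qs) lapply(qs, function(q)
    list(q$chr, q$start, q$end, sort(q$members$snp)))
  expect_equal(key(q1), key(q2))
})

test_that("size_mb is consistent with interval bounds", {
  a <- make_assoc(c(2e6, 2.1e6, 2.2e6), 6)
  q <- merge_panels(call_clusters(a))[[1]]
  expect_equal(q$size_mb, qtl_size_mb(q$start, q$end))
  expect_equal(q$size_mb, round((q$end - q$start) / 1e6, 3))
})

test_that("peak selection maximises significance with deterministic ties", {
  a <- make_assoc(c(1e6, 1.05e6, 1.1e6), c(5.2, 7.8, 6.1))
  q <- merge_panels(call_clusters(a))[[1]]
  expect_equal(q$peak$minus_log10_p, 7.8)
  tie <- make_assoc(c(100, 200), c(6, 6))
  qt <- merge_panels(call_clusters(tie))[[1]]
  expect_equal(qt$peak$pos, 100)
  single <- call_clusters(make_assoc(5e5, 9))[[1]]
  expect_equal(pick_peak(single)$pos, 5e5)
  expect_error(pick_peak(list(members = NULL)), "empty")
})

test_that("naming adds ordinals only for multi-QTL chromosomes", {
  q9a <- merge_panels(call_clusters(make_assoc(c(1e6, 1.1e6), 6, chr = 9)))
  q9b <- merge_panels(call_clusters(make_assoc(c(9e6, 9.1e6), 6, chr = 9)))
  q12 <- merge_panels(call_clusters(make_assoc(c(2e6, 2.1e6), 6, chr = 12)))
  nm <- assign_names(c(q9a, q9b, q12), trait_symbol = "Si")
  expect_equal(vapply(nm, function(q) q$name, ""),
               c("qSi9-1", "qSi9-2", "qSi12"))
  expect_equal(assign_names(list()), list())
})

test_that("co-location uses span overlap or a 500 kb end gap", {
  mk <- function(pos, trait, chr = 1, name = trait) {
    # dense SNP string across [pos1, pos2] so one cluster covers the span
    string <- unique(c(seq(pos[1], pos[2], by = 150000), pos[2]))
    q <- merge_panels(call_clusters(make_assoc(string, 6, chr = chr,
                                               trait = trait)))[[1]]
    q$name <- name
    q
  }
  # published interval pair: StHD 22,692,755-24,617,484 overlaps As
  # 21,981,983-24,449,843 (gap 0)
  st <- mk(c(22742755, 24567484), "StHD")
  as_ <- mk(c(22031983, 24399843), "As")
  cc <- coloc(list(st), list(as_))
  expect_equal(nrow(cc), 1)
  expect_equal(cc$gap, 0)
  expect_equal(cc$basis, "interspersed")

  a <- mk(c(1e6, 1.95e6), "A")
  b <- mk(c(2.45e6, 3e6), "B")
  cc2 <- coloc(list(a), list(b))
  expect_equal(nrow(cc2), 1)
  expect_equal(cc2$basis, "end_gap")
  expect_lte(cc2$gap, 500000)

  b2 <- mk(c(2.75e6, 3e6), "B")   # end gap 600 kb
  expect_equal(nrow(coloc(list(a), list(b2))), 0)

  # symmetry
  cc3 <- coloc(list(b), list(a))
  expect_equal(sort(c(cc3$qtl_a, cc3$qtl_b)), sort(c(cc2$qtl_a, cc2$qtl_b)))
  expect_error(coloc(list(a), list(a)), "different traits")
})

test_that("pivot tables report allele means, differences and concordance", {
  M <- matrix(c(0L, 0L, 2L, 2L, 2L), ncol = 1,
              dimnames = list(paste0("a", 1:5), "s1"))
  G <- structure(list(dosages = M,
                      map = data.frame(snp = "s1", chr = 1, pos = 100,
                                       ref = "A", alt = "G"),
                      subpop = NULL, inbred = TRUE),
                 class = "genotype_matrix")
  tm <- cbind(T1 = c(10, 12, 20, 22, 24), T2 = c(5, 5, 1, 2, 3),
              T3 = c(7, 7, 7, 7, 7))
  rownames(tm) <- paste0("a", 1:5)
  peak <- data.frame(snp = "s1", trait = "T1", common_allele = "G",
                     stringsAsFactors = FALSE)
  pv <- pivot_allele_effects(peak, G, tm)
  # common allele G carried by a3..a5 (dosage 2)
  expect_equal(pv$mean_common[pv$trait == "T1"], 22)
  expect_equal(pv$mean_alt[pv$trait == "T1"], 11)
  expect_equal(pv$diff[pv$trait == "T1"], 11)
  expect_equal(pv$diff[pv$trait == "T3"], 0)
  expect_true(pv$concordant[pv$trait == "T1"])
  expect_false(pv$concordant[pv$trait == "T2"])  # opposite direction
})

test_that("planted pleiotropic QTL give concordant pivot signs", {
  hits <- 0
  for (s in 1:20) {
    G <- small_panel(n = 120, n_snps = 60, fst = 0.05, seed = 1500 + s)
    f <- colMeans(G$dosages) / 2
    j <- which.min(abs(f - 0.4))
    truth <- truth_set(c("T1", "T2"),
                       qtl = data.frame(trait = c("T1", "T2"),
                                        chr = G$map$chr[j], pos = G$map$pos[j],
                                        effect = c(0.9, 0.7)),
                       polygenic_sd = 0.5, env_sd = 0.1, noise_sd = 0.3)
    recs <- simulate_traits(G, truth, seed = s)
    tm <- trait_matrix(recs)
    st <- allele_stats(G, G$map$snp[j])
    peak <- data.frame(snp = G$map$snp[j], trait = "T1",
                       common_allele = st$common_allele,
                       stringsAsFactors = FALSE)
    pv <- pivot_allele_effects(peak, G, tm)
    hits <- hits + isTRUE(pv$concordant[pv$trait == "T2"])
  }
  expect_gte(hits / 20, 0.9)
})

test_that("gene proximity respects the 1 Mb window and distance sort", {
  q <- merge_panels(call_clusters(make_assoc(c(5e6, 5.1e6), 6)))[[1]]
  q$name <- "qX1"
  ann <- data.frame(
    gene = c("inside", "near", "far", "edge"),
    chr = 1,
    start = c(5.05e6, q$end + 900000, q$end + 1000001, q$end + 1000000),
    end = c(5.06e6, q$end + 910000, q$end + 1000101, q$end + 1000100),
    description = "x", stringsAsFactors = FALSE)
  out <- genes_near(list(q), ann)
  expect_equal(out$gene, c("inside", "near", "edge"))
  expect_equal(out$distance[1], 0)
  expect_false("far" %in% out$gene)
  expect_warning(genes_near(list(q), transform(ann, chr = 2)),
                 "chromosome")
})
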