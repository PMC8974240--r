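# Rule-based QTL region declaration from association records: greedy
# clustering of significant SNPs, flanking, stringency flags, peak SNP,
# cross-panel merging with effect-sign splitting, naming, cross-trait
# co-location, pivot allele effects, and gene proximity annotation.
# All coordinates are 1-based and inclusive on both ends, matching the
# convention of printed QTL tables; BED export converts explicitly.

#' Cluster significant SNPs into candidate regions
#'
#' SNPs with `minus_log10_p > threshold` are greedily chained per chromosome:
#' a significant SNP joins the current cluster when its gap to the previous
#' significant SNP is at most `extend`. Each cluster's region is the
#' significant-SNP span widened by `flank` on both sides and clamped at
#' position 1.
#'
#' @param assoc `assoc_records` data.frame from [mlm_scan()]
#' @param threshold significance threshold on -log10(p) (default 5)
#' @param extend maximum gap between consecutive significant SNPs in one
#'   cluster, bp (default 200 kb)
#' @param flank region extension around the SNP span, bp (default 50 kb)
#' @return list of `sig_cluster` objects (trait, panel, chr, members,
#'   snp_span, region, flags)
#' @export
call_clusters <- function(assoc, threshold = 5.0, extend = 200000,
                          flank = 50000) {
  sig <- assoc[assoc$minus_log10_p > threshold, , drop = FALSE]
  if (!nrow(sig)) return(list())
  sig <- sig[order(sig$chr, sig$pos), , drop = FALSE]
  out <- list()
  for (ch in unique(sig$chr)) {
    s <- sig[sig$chr == ch, , drop = FALSE]
    grp <- cumsum(c(1, diff(s$pos) > extend))
    for (g in unique(grp)) {
      mem <- s[grp == g, , drop = FALSE]
      span <- range(mem$pos)
      cl <- structure(list(
        trait = mem$trait[1], panel = mem$panel[1], chr = ch,
        members = mem, snp_span = span,
        region = c(max(1, span[1] - flank), span[2] + flank),
        flags = c(single_snp = nrow(mem) < 2,
                  all_rare = all(mem$n_alt < 6))), class = "sig_cluster")
      out[[length(out) + 1]] <- cl
    }
  }
  out
}

#' Apply claim-stringency flags to clusters
#'
#' Regions where only one SNP met the significance threshold, or where every
#' associated SNP has a rare alternate allele (carried by fewer than
#' `min_alt_carriers` accessions), are flagged and excluded from claims but
#' retained for diagnostics.
#'
#' @param clusters list of clusters from [call_clusters()]
#' @param min_snps minimum member SNPs for a claim (default 2)
#' @param min_alt_carriers rare-allele carrier threshold (default 6)
#' @return the clusters with updated `flags` and a `claimed` element
#' @export
apply_stringency <- function(clusters, min_snps = 2, min_alt_carriers = 6) {
  lapply(clusters, function(cl) {
    cl$flags["single_snp"] <- nrow(cl$members) < min_snps
    cl$flags["all_rare"] <- all(cl$members$n_alt < min_alt_carriers)
    cl$claimed <- !any(cl$flags)
    cl
  })
}

# orient member effect signs to the allele most common in the reference
# (full-panel) genotype set, so sign consistency is well defined across
# panels whose common allele differs
orient_signs <- function(members, ref_common = NULL) {
  s <- sign(members$effect_common)
  if (!is.null(ref_common)) {
    rc <- ref_common[members$snp]
    flip <- !is.na(rc) & rc != members$common_allele
    s[flip] <- -s[flip]
  }
  s
}

#' Merge same-trait clusters across panels into declared QTL
#'
#' All member SNPs of all clusters for one trait are pooled per chromosome
#' and chained: consecutive significant SNPs separated by more than
#' `merge_gap` start a new QTL, and a change in the (reference-oriented)
#' additive effect sign inside a chain splits it at the boundary between the
#' last SNP of one sign and the first of the other. The declared region is
#' the union of member cluster regions (SNP span +/- `flank`).
#'
#' @param clusters list of same-trait clusters (possibly from many panels)
#' @param merge_gap maximum gap between significant-SNP spans, bp (800 kb)
#' @param flank flank used for the merged region, bp (default 50 kb)
#' @param ref_common optional named vector snp -> common allele in the full
#'   panel, used to orient effect signs before the consistency check
#' @param min_snps,min_alt_carriers stringency thresholds re-applied to the
#'   merged QTL
#' @return list of `qtl_region` objects
#' @export
merge_panels <- function(clusters, merge_gap = 800000, flank = 50000,
                         ref_common = NULL, min_snps = 2,
                         min_alt_carriers = 6) {
  if (!length(clusters)) return(list())
  trait <- unique(vapply(clusters, function(c) c$trait, ""))
  if (length(trait) > 1) stopf("merge_panels expects same-trait clusters")
  mem <- do.call(rbind, lapply(clusters, function(c) c$members))
  mem <- mem[!duplicated(mem[c("snp", "panel")]), , drop = FALSE]
  out <- list()
  for (ch in sort(unique(mem$chr))) {
    s <- mem[mem$chr == ch, , drop = FALSE]
    s <- s[order(s$pos, s$panel), , drop = FALSE]
    gap_break <- c(FALSE, diff(s$pos) > merge_gap)
    sgn <- orient_signs(s, ref_common)
    sign_break <- c(FALSE, sgn[-1] != sgn[-length(sgn)] &
                      sgn[-1] != 0 & sgn[-length(sgn)] != 0)
    grp <- cumsum(gap_break | sign_break)
    for (g in unique(grp)) {
      m <- s[grp == g, , drop = FALSE]
      span <- range(m$pos)
      q <- structure(list(
        name = NA_character_, trait = trait, chr = ch,
        start = max(1, span[1] - flank), end = span[2] + flank,
        snp_span = span, members = m,
        panels = sort(unique(m$panel)),
        peak = NULL, effect_sign = NA_real_,
        flags = c(single_snp = nrow(m) < min_snps,
                  all_rare = all(m$n_alt < min_alt_carriers))),
        class = "qtl_region")
      q$size_mb <- qtl_size_mb(q$start, q$end)
      q$peak <- pick_peak(q)
      q$effect_sign <- sign(q$peak$effect_common)
      q$claimed <- !any(q$flags)
      out[[length(out) + 1]] <- q
    }
  }
  out
}

#' Peak SNP of a QTL region
#'
#' The member SNP with the largest -log10(p); ties broken by smaller
#' position, then lexicographic panel name.
#'
#' @param qtl a `qtl_region` (or `sig_cluster`)
#' @return one-row data.frame (an AssocRecord)
#' @export
pick_peak <- function(qtl) {
  m <- qtl$members
  if (is.null(m) || !nrow(m)) stopf("empty QTL region has no peak")
  o <- order(-m$minus_log10_p, m$pos, m$panel)
  m[o[1], , drop = FALSE]
}

#' Assign serial QTL names per trait
#'
#' Names follow the `q<Trait><chr>` convention, with an ordinal `-k` suffix
#' (by start position) appended only when a chromosome carries more than one
#' QTL for the trait.
#'
#' @param qtls list of `qtl_region`s for one trait
#' @param trait_symbol symbol used in names (default: the trait itself)
#' @param claimed_only number only claimed QTL (default TRUE; flagged ones
#'   get the suffix "(not claimed)")
#' @return the list with `name` fields filled in, ordered chr then start
#' @export
assign_names <- function(qtls, trait_symbol = NULL, claimed_only = TRUE) {
  if (!length(qtls)) return(qtls)
  trait_symbol <- trait_symbol %||% qtls[[1]]$trait
  ord <- order(vapply(qtls, function(q) q$chr, 0),
               vapply(qtls, function(q) q$start, 0))
  qtls <- qtls[ord]
  use <- if (claimed_only)
    vapply(qtls, function(q) isTRUE(q$claimed %||% TRUE), TRUE)
  else rep(TRUE, length(qtls))
  chrs <- vapply(qtls, function(q) q$chr, 0)
  for (ch in unique(chrs)) {
    idx <- which(chrs == ch & use)
    for (k in seq_along(idx)) {
      qtls[[idx[k]]]$name <- if (length(idx) > 1)
        sprintf("q%s%d-%d", trait_symbol, ch, k)
      else sprintf("q%s%d", trait_symbol, ch)
    }
    for (i in which(chrs == ch & !use))
      qtls[[i]]$name <- sprintf("q%s%d (not claimed)", trait_symbol, ch)
  }
  qtls
}

#' Co-location of QTL across two traits
#'
#' Two QTL of different traits are co-located when their significant-SNP
#' spans overlap (interspersed) or when the ends of their regions are at most
#' `end_gap` apart. With `strict = TRUE` the interspersed basis additionally
#' requires the spans to interleave (a SNP of each trait inside the other's
#' span) rather than merely overlap.
#'
#' @param qtls_a,qtls_b lists of `qtl_region`s for two different traits
#' @param end_gap maximum end-to-end gap, bp (default 500 kb)
#' @param strict require interleaving for the interspersed basis
#' @return data.frame: qtl_a, qtl_b, basis (`interspersed` or `end_gap`),
#'   gap (bp, 0 when overlapping)
#' @export
coloc <- function(qtls_a, qtls_b, end_gap = 500000, strict = FALSE) {
  res <- data.frame(qtl_a = character(), qtl_b = character(),
                    basis = character(), gap = numeric(),
                    stringsAsFactors = FALSE)
  for (qa in qtls_a) for (qb in qtls_b) {
    if (qa$chr != qb$chr) next
    if (identical(qa$trait, qb$trait)) stopf("coloc requires different traits")
    span_overlap <- qa$snp_span[1] <= qb$snp_span[2] &&
      qb$snp_span[1] <= qa$snp_span[2]
    if (strict && span_overlap) {
      a_in_b <- any(qa$members$pos >= qb$snp_span[1] &
                    qa$members$pos <= qb$snp_span[2])
      b_in_a <- any(qb$members$pos >= qa$snp_span[1] &
                    qb$members$pos <= qa$snp_span[2])
      span_overlap <- a_in_b && b_in_a
    }
    gap <- max(0, max(qa$start, qb$start) - min(qa$end, qb$end))
    if (span_overlap) {
      res[nrow(res) + 1, ] <- list(qa$name, qb$name, "interspersed", 0)
    } else if (gap <= end_gap) {
      res[nrow(res) + 1, ] <- list(qa$name, qb$name, "end_gap", gap)
    }
  }
  res
}

#' Peak-allele pivot table across traits
#'
#' For the peak SNP of a QTL, compares trait means between carriers of the
#' common and the alternate allele for each requested trait, and flags sign
#' concordance: whether the allele that decreases the anchor trait also
#' decreases each other trait.
#'
#' @param peak one-row AssocRecord (e.g. `qtl$peak`)
#' @param G a `genotype_matrix` containing the peak SNP
#' @param tm accession x trait matrix ([trait_matrix()])
#' @param traits traits to tabulate (default: all columns of `tm`)
#' @param anchor trait whose allele effect direction anchors the concordance
#'   flag (default: the peak's own trait)
#' @return data.frame: trait, mean_common, mean_alt, diff (common - alt),
#'   sign, concordant, estimable
#' @export
pivot_allele_effects <- function(peak, G, tm, traits = NULL, anchor = NULL) {
  traits <- traits %||% colnames(tm)
  anchor <- anchor %||% peak$trait
  j <- match(peak$snp, G$map$snp)
  if (is.na(j)) stopf("peak SNP %s not genotyped in this panel", peak$snp)
  d <- G$dosages[, j]
  common_is_alt <- G$map$alt[j] == peak$common_allele
  carr_common <- names(d)[!is.na(d) & d == (if (common_is_alt) 2 else 0)]
  carr_alt <- names(d)[!is.na(d) & d == (if (common_is_alt) 0 else 2)]
  carr_common <- intersect(carr_common, rownames(tm))
  carr_alt <- intersect(carr_alt, rownames(tm))
  rows <- lapply(traits, function(t) {
    est <- length(carr_common) > 0 && length(carr_alt) > 0
    mc <- if (length(carr_common)) mean(tm[carr_common, t], na.rm = TRUE) else NA_real_
    ma <- if (length(carr_alt)) mean(tm[carr_alt, t], na.rm = TRUE) else NA_real_
    diff <- mc - ma
    data.frame(trait = t, mean_common = mc, mean_alt = ma, diff = diff,
               sign = sign(diff), estimable = est, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  a <- out$sign[out$trait == anchor]
  if (length(a) == 1 && !is.na(a) && a != 0) {
    out$concordant <- out$estimable & !is.na(out$sign) & out$sign == a
  } else {
    out$concordant <- NA
  }
  out
}

#' Genes near QTL regions
#'
#' Annotated genes whose interval lies within `window` of a QTL interval
#' (distance 0 for overlap), sorted by distance.
#'
#' @param qtls list of `qtl_region`s
#' @param annotations data.frame: gene, chr, start, end, description
#' @param window maximum interval distance, bp (default 1 Mb)
#' @return data.frame: qtl, gene, chr, gene_start, gene_end, distance,
#'   description
#' @export
genes_near <- function(qtls, annotations, window = 1e6) {
  stopifnot(all(c("gene", "chr", "start", "end") %in% names(annotations)))
  if (any(annotations$end < annotations$start))
    stopf("gene annotation with end < start")
  qchr <- unique(vapply(qtls, function(q) as.character(q$chr), ""))
  unmatched <- setdiff(qchr, as.character(unique(annotations$chr)))
  if (length(unmatched))
    warnf("no annotations on chromosome(s): %s",
          paste(unmatched, collapse = ", "))
  out <- list()
  for (q in qtls) {
    a <- annotations[as.character(annotations$chr) == as.character(q$chr), ,
                     drop = FALSE]
    if (!nrow(a)) next
    dist <- pmax(0, pmax(q$start - a$end, a$start - q$end))
    keep <- dist <= window
    if (!any(keep)) next
    a <- a[keep, , drop = FALSE]; dist <- dist[keep]
    o <- order(dist, a$start)
    out[[length(out) + 1]] <- data.frame(
      qtl = q$name %||% NA_character_, gene = a$gene[o], chr = q$chr,
      gene_start = a$start[o], gene_end = a$end[o], distance = dist[o],
      description = if ("description" %in% names(a)) a$description[o] else "",
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(qtl = character(), gene = character(), chr = integer(),
                      gene_start = integer(), gene_end = integer(),
                      distance = numeric(), description = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Full region-calling pipeline for one trait
#'
#' Convenience wrapper: cluster each panel's records, merge across panels,
#' apply stringency, and name the claimed QTL.
#'
#' @param assoc_list list of `assoc_records` (one per panel) for one trait
#' @param threshold,extend,flank,merge_gap,min_snps,min_alt_carriers rule
#'   parameters (defaults 5, 200 kb, 50 kb, 800 kb, 2, 6)
#' @param ref_common optional snp -> full-panel common allele map
#' @param trait_symbol symbol for QTL names
#' @return list of named `qtl_region`s (claimed and flagged)
#' @export
call_qtl <- function(assoc_list, threshold = 5.0, extend = 200000,
                     flank = 50000, merge_gap = 800000, min_snps = 2,
                     min_alt_carriers = 6, ref_common = NULL,
                     trait_symbol = NULL) {
  clusters <- unlist(lapply(assoc_list, call_clusters, threshold = threshold,
                            extend = extend, flank = flank), recursive = FALSE)
  if (!length(clusters)) return(list())
  qtls <- merge_panels(clusters, merge_gap = merge_gap, flank = flank,
                       ref_common = ref_common, min_snps = min_snps,
                       min_alt_carriers = min_alt_carriers)
  assign_names(qtls, trait_symbol = trait_symbol)
}
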