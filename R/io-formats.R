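# Readers and writers: HapMap text, VCF, long-format phenotype TSV, trait
# matrix TSV, gene annotations (GFF3 via rtracklayer, or TSV), QTL report
# TSV + BED, DAG exports. Internal coordinates are 1-based inclusive; only
# the BED export converts to 0-based half-open.

provenance_header <- function(seed = NULL, params = NULL) {
  h <- sprintf("# panelgwas %s",
               as.character(utils::packageVersion("panelgwas")))
  if (!is.null(seed)) h <- paste0(h, sprintf(" seed=%s", seed))
  if (!is.null(params))
    h <- paste0(h, sprintf(" params=%s",
                           substr(rlang_hash(params), 1, 8)))
  h
}

# tiny stable hash (sum of utf8 codes of the serialised params); enough for
# a provenance fingerprint without extra dependencies
rlang_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 0xffffffff)
}

write_tsv_prov <- function(df, path, seed = NULL, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_prov <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' Write genotypes as HapMap text
#'
#' Standard tab-delimited HapMap layout (`rs#`, `alleles`, `chrom`, `pos`,
#' strand/assembly/QC filler columns, then one two-letter genotype column per
#' accession; `NN` = missing).
#'
#' @param G a `genotype_matrix`
#' @param path output path
#' @export
write_hapmap <- function(G, path) {
  m <- G$map
  acc <- rownames(G$dosages)
  code <- matrix("NN", nrow = nrow(m), ncol = length(acc))
  for (j in seq_len(nrow(m))) {
    d <- G$dosages[, j]
    code[j, ] <- ifelse(is.na(d), "NN",
                 ifelse(d == 2, strrep(m$alt[j], 2),
                 ifelse(d == 0, strrep(m$ref[j], 2),
                        paste0(m$ref[j], m$alt[j]))))
  }
  hdr <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#", "center",
           "protLSID", "assayLSID", "panelLSID", "QCcode", acc)
  body <- cbind(m$snp, paste(m$ref, m$alt, sep = "/"), m$chr, m$pos, "+",
                "NA", "NA", "NA", "NA", "NA", "NA", code)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genotypes from HapMap text
#'
#' @param path HapMap file
#' @param inbred_strict treat heterozygote codes as missing with a warning
#'   (default `TRUE`, matching homozygous inbred panels); otherwise dosage 1
#' @return a `genotype_matrix`
#' @export
read_hapmap <- function(path, inbred_strict = TRUE) {
  first <- readLines(path, n = 1)
  hdr <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 12 || hdr[1] != "rs#" || hdr[3] != "chrom" ||
      hdr[4] != "pos")
    stopf("malformed HapMap header at line 1 of %s", path)
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  acc <- hdr[-(1:11)]
  alleles <- strsplit(x$alleles, "/", fixed = TRUE)
  multi <- lengths(alleles) != 2
  if (any(multi)) {
    warnf("skipping %d non-biallelic HapMap rows", sum(multi))
    x <- x[!multi, , drop = FALSE]; alleles <- alleles[!multi]
  }
  ref <- vapply(alleles, `[`, "", 1)
  alt <- vapply(alleles, `[`, "", 2)
  codes <- as.matrix(x[, acc, drop = FALSE])
  n <- length(acc); m <- nrow(x)
  dos <- matrix(NA_integer_, nrow = n, ncol = m,
                dimnames = list(acc, x[["rs#"]]))
  het_seen <- FALSE
  for (j in seq_len(m)) {
    cj <- codes[j, ]
    d <- rep(NA_integer_, n)
    d[cj == strrep(ref[j], 2)] <- 0L
    d[cj == strrep(alt[j], 2)] <- 2L
    het <- cj %in% c(paste0(ref[j], alt[j]), paste0(alt[j], ref[j]))
    if (any(het)) {
      het_seen <- TRUE
      d[het] <- if (inbred_strict) NA_integer_ else 1L
    }
    dos[, j] <- d
  }
  if (het_seen && inbred_strict)
    warnf("heterozygote codes set to missing under inbred-strict mode")
  structure(list(dosages = dos,
                 map = data.frame(snp = x[["rs#"]], chr = x$chrom,
                                  pos = x$pos, ref = ref, alt = alt,
                                  stringsAsFactors = FALSE),
                 subpop = NULL, inbred = inbred_strict),
            class = "genotype_matrix")
}

#' Write genotypes as VCF 4.2
#' @param G a `genotype_matrix`
#' @param path output path (plain text `.vcf`)
#' @export
write_vcf <- function(G, path) {
  m <- G$map
  acc <- rownames(G$dosages)
  gt <- matrix(".", nrow = nrow(m), ncol = length(acc))
  for (j in seq_len(nrow(m))) {
    d <- G$dosages[, j]
    gt[j, ] <- ifelse(is.na(d), "./.",
               ifelse(d == 2, "1/1", ifelse(d == 0, "0/0", "0/1")))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", acc), collapse = "\t")), con)
  body <- cbind(m$chr, m$pos, m$snp, m$ref, m$alt, ".", "PASS", ".", "GT", gt)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Uses `VariantAnnotation::readVcf()` when available (any valid VCF 4.x),
#' with a minimal fallback parser for plain-text single-FORMAT files.
#' `0/0 -> 0`, `1/1 -> 2`, `0/1 -> 1` (set missing with a warning under
#' `inbred_strict`), `./. -> NA`; multi-allelic records are skipped with a
#' reported count.
#'
#' @param path VCF path
#' @param inbred_strict heterozygotes treated as missing (default `TRUE`)
#' @return a `genotype_matrix`
#' @export
read_vcf <- function(path, inbred_strict = TRUE) {
  if (requireNamespace("VariantAnnotation", quietly = TRUE)) {
    v <- VariantAnnotation::readVcf(path)
    if (!("GT" %in% names(VariantAnnotation::geno(v))))
      stopf("VCF %s has no GT field", path)
    rr <- SummarizedExperiment::rowRanges(v)
    altlist <- VariantAnnotation::alt(v)
    multi <- lengths(altlist) != 1
    if (any(multi)) warnf("skipping %d multi-allelic VCF records", sum(multi))
    keep <- which(!multi)
    gt <- VariantAnnotation::geno(v)$GT[keep, , drop = FALSE]
    chrv <- as.character(GenomeInfoDb::seqnames(rr))[keep]
    posv <- BiocGenerics::start(rr)[keep]
    refv <- as.character(VariantAnnotation::ref(v))[keep]
    altv <- as.character(unlist(altlist[keep]))
    ids <- names(rr)[keep]
  } else {
    lines <- readLines(path)
    hline <- grep("^#CHROM", lines)
    if (!length(hline)) stopf("no #CHROM header in %s", path)
    hdr <- strsplit(lines[hline], "\t", fixed = TRUE)[[1]]
    rows <- strsplit(lines[(hline + 1):length(lines)], "\t", fixed = TRUE)
    rows <- rows[lengths(rows) == length(hdr)]
    tab <- do.call(rbind, rows)
    if (!any(grepl("GT", tab[, 9]))) stopf("VCF %s has no GT field", path)
    multi <- grepl(",", tab[, 5], fixed = TRUE)
    if (any(multi)) warnf("skipping %d multi-allelic VCF records", sum(multi))
    tab <- tab[!multi, , drop = FALSE]
    gt <- sub(":.*", "", tab[, -(1:9), drop = FALSE])
    rownames(gt) <- tab[, 3]
    colnames(gt) <- hdr[-(1:9)]
    chrv <- tab[, 1]; posv <- as.integer(tab[, 2]); refv <- tab[, 4]
    altv <- tab[, 5]; ids <- tab[, 3]
  }
  gt <- sub(":.*", "", gt)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), ids))
  dos[t(gt == "0/0")] <- 0L
  dos[t(gt == "1/1")] <- 2L
  het <- t(gt == "0/1" | gt == "1/0")
  if (any(het)) {
    if (inbred_strict) {
      warnf("%d heterozygous calls set to missing under inbred-strict mode",
            sum(het))
    } else dos[het] <- 1L
  }
  chr_clean <- suppressWarnings(as.integer(sub("^[Cc]hr", "", chrv)))
  structure(list(dosages = dos,
                 map = data.frame(snp = ids,
                                  chr = if (anyNA(chr_clean)) chrv else chr_clean,
                                  pos = posv, ref = refv, alt = altv,
                                  stringsAsFactors = FALSE),
                 subpop = NULL, inbred = inbred_strict),
            class = "genotype_matrix")
}

#' Write / read long-format phenotype records as TSV
#' @param records `replicated_phenotypes` data.frame
#' @param path TSV path
#' @param seed seed recorded in the provenance header
#' @export
write_phenotypes <- function(records, path, seed = NULL) {
  write_tsv_prov(as.data.frame(records), path, seed = seed)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  d <- read_tsv_prov(path)
  class(d) <- c("replicated_phenotypes", "data.frame")
  d
}

#' Write / read a trait matrix as TSV with a transform metadata line
#' @param tm matrix from [trait_matrix()]
#' @param path TSV path
#' @export
write_trait_matrix <- function(tm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(), con)
  tg <- attr(tm, "transform") %||%
    stats::setNames(rep("identity", ncol(tm)), colnames(tm))
  writeLines(paste0("# transform: ",
                    paste(sprintf("%s=%s", names(tg), tg), collapse = ",")),
             con)
  utils::write.table(data.frame(accession = rownames(tm), tm,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_matrix
#' @export
read_trait_matrix <- function(path) {
  lines <- readLines(path, n = 5)
  tline <- grep("^# transform:", lines, value = TRUE)
  d <- read_tsv_prov(path, check.names = FALSE)
  tm <- as.matrix(d[, -1, drop = FALSE])
  rownames(tm) <- d$accession
  if (length(tline)) {
    kv <- strsplit(strsplit(sub("^# transform: *", "", tline[1]), ",")[[1]], "=")
    tags <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
    attr(tm, "transform") <- tags
  }
  tm
}

#' Read gene annotations from GFF3 or TSV
#'
#' GFF3 files (`.gff`, `.gff3`, via `rtracklayer::import`) are reduced to
#' gene-type records; TSV files must carry columns gene, chr, start, end and
#' optionally description. Chromosome names are normalised by stripping a
#' `chr` prefix.
#'
#' @param path annotation file
#' @return data.frame: gene, chr, start, end, description
#' @export
read_gene_annotations <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stopf("reading GFF3 requires the rtracklayer package")
    g <- rtracklayer::import(path)
    g <- g[g$type %in% c("gene", "pseudogene")]
    id <- g$ID %||% g$Name %||% sprintf("gene%05d", seq_along(g))
    out <- data.frame(
      gene = as.character(id),
      chr = sub("^[Cc]hr", "", as.character(GenomicRanges::seqnames(g))),
      start = GenomicRanges::start(g), end = GenomicRanges::end(g),
      description = as.character(g$Note %||% g$description %||% ""),
      stringsAsFactors = FALSE)
  } else {
    out <- read_tsv_prov(path)
    stopifnot(all(c("gene", "chr", "start", "end") %in% names(out)))
    out$chr <- sub("^[Cc]hr", "", as.character(out$chr))
    if (is.null(out$description)) out$description <- ""
  }
  cn <- suppressWarnings(as.integer(out$chr))
  if (!anyNA(cn)) out$chr <- cn
  out
}

#' QTL report writer (summary-table column order) with BED companion
#'
#' The TSV mirrors the published summary-table layout: QTL, chr, start, end,
#' size (Mb), peak SNP location, panel, -log10(p), effect of the most common
#' allele, alleles, carrier counts, alternate-allele percentage, and
#' co-located traits. The BED companion converts 1-based inclusive intervals
#' to 0-based half-open (`start - 1`, `end`).
#'
#' @param qtls list of named `qtl_region`s (any traits)
#' @param colocs optional data.frame from [coloc()] used to fill the
#'   overlaps column
#' @param path output TSV path; the BED companion replaces the extension
#' @param seed provenance seed
#' @return invisible named vector of the two paths
#' @export
write_qtl_report <- function(qtls, colocs = NULL, path, seed = NULL) {
  rows <- lapply(qtls, function(q) {
    pk <- q$peak
    ov <- ""
    if (!is.null(colocs) && nrow(colocs)) {
      hit <- colocs[colocs$qtl_a == q$name | colocs$qtl_b == q$name, ,
                    drop = FALSE]
      other <- setdiff(unique(c(hit$qtl_a, hit$qtl_b)), q$name)
      ov <- paste(other, collapse = ",")
    }
    data.frame(qtl = q$name, trait = q$trait, chr = q$chr, start = q$start,
               end = q$end, size_mb = q$size_mb, peak_pos = pk$pos,
               panel = pk$panel, minus_log10_p = pk$minus_log10_p,
               effect_common = pk$effect_common,
               common_allele = pk$common_allele, alt_allele = pk$alt_allele,
               n_common = pk$n_common, n_alt = pk$n_alt, pct_alt = pk$pct_alt,
               claimed = isTRUE(q$claimed %||% TRUE), overlaps = ov,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(qtl = character(), trait = character(), chr = integer(),
               start = integer(), end = integer(), size_mb = numeric(),
               peak_pos = integer(), panel = character(),
               minus_log10_p = numeric(), effect_common = numeric(),
               common_allele = character(), alt_allele = character(),
               n_common = integer(), n_alt = integer(), pct_alt = numeric(),
               claimed = logical(), overlaps = character(),
               stringsAsFactors = FALSE)
  write_tsv_prov(df, path, seed = seed)
  bed_path <- sub("\\.[^.]*$", ".bed", path)
  if (identical(bed_path, path)) bed_path <- paste0(path, ".bed")
  bed <- if (nrow(df))
    data.frame(chr = df$chr, start = df$start - 1, end = df$end,
               name = df$qtl)
  else data.frame(chr = integer(), start = integer(), end = integer(),
                  name = character())
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(tsv = path, bed = bed_path))
}

#' Export a trait DAG as an arc-list TSV and Graphviz DOT
#' @param dag a `trait_dag`
#' @param path TSV path; the DOT companion replaces the extension
#' @export
write_dag <- function(dag, path) {
  arcs <- dag$arcs
  if (is.null(arcs$strength)) arcs$strength <- NA_real_
  write_tsv_prov(arcs[c("from", "to", "strength", "coef")], path)
  dot_path <- sub("\\.[^.]*$", ".dot", path)
  lines <- c("digraph traits {",
             sprintf("  \"%s\";", dag$nodes),
             if (nrow(arcs))
               sprintf("  \"%s\" -> \"%s\" [label=\"%.2f\"];",
                       arcs$from, arcs$to, arcs$coef),
             "}")
  writeLines(lines, dot_path)
  invisible(c(tsv = path, dot = dot_path))
}
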