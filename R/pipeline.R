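# Configuration container and the end-to-end pipeline: simulate (optional)
# -> phenotype statistics -> per-panel per-trait MLM scans -> QTL regions ->
# co-location / pivot -> gene annotation -> trait network.

#' Pipeline configuration
#'
#' All thresholds default to the standard region-calling rules: significance
#' -log10(p) > 5, cluster extension 200 kb, 50 kb flanks, 800 kb cross-panel
#' merge gap, 500 kb co-location end gap, 1 Mb gene window, claims need at
#' least 2 SNPs and 6 alternate-allele carriers.
#'
#' @param genotypes,phenotypes,annotations optional input paths (HapMap/VCF,
#'   long TSV, GFF3/TSV); `NULL` plus `simulate = TRUE` generates inputs
#' @param outdir output directory
#' @param simulate generate a synthetic panel instead of reading inputs
#' @param sim_config [panel_config()] for simulation
#' @param traits traits to scan (default: all in the phenotypes)
#' @param panels named list of [panel_def()]s; `NULL` derives
#'   [default_panels()] from the genotype subpopulation labels
#' @param sig,extend,flank,merge_gap,coloc_gap,gene_window,min_snps,min_alt_carriers
#'   region-calling parameters
#' @param bn a [bn_config()]
#' @param run_bn,run_annotate toggles for the optional stages
#' @param seed master seed for all stochastic stages
#' @param stop_after run only through the named stage (`"all"` default;
#'   `"simulate"`, `"pheno"`, `"gwas"`, `"regions"`); used by the CLI
#'   subcommands
#' @param bn_only skip the association and region stages and learn the trait
#'   network straight from the trait matrix (the CLI `bn` subcommand)
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(genotypes = NULL, phenotypes = NULL,
                            annotations = NULL, outdir = tempfile("panelgwas"),
                            simulate = is.null(genotypes),
                            sim_config = panel_config(),
                            traits = NULL, panels = NULL,
                            sig = 5.0, extend = 200000, flank = 50000,
                            merge_gap = 800000, coloc_gap = 500000,
                            gene_window = 1e6, min_snps = 2,
                            min_alt_carriers = 6,
                            bn = bn_config(), run_bn = TRUE,
                            run_annotate = !is.null(annotations), seed = 1,
                            stop_after = c("all", "simulate", "pheno",
                                           "gwas", "regions"),
                            bn_only = FALSE) {
  stop_after <- match.arg(stop_after)
  stopifnot(sig > 0, extend > 0, flank > 0, merge_gap > 0, coloc_gap > 0,
            gene_window > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stages: (1) simulate or read genotypes/phenotypes; (2) BLUP trait matrix
#' with log transform of skewed element traits; (3) per-panel kinship, PCA
#' and MLM scans for each trait; (4) QTL region calling with cross-panel
#' merging; (5) cross-trait co-location and peak pivot tables; (6) candidate
#' gene annotation (optional); (7) cross-validated trait network (optional).
#' All outputs are TSV/BED/JSON files under `config$outdir` with provenance
#' headers; identical seeds give byte-identical outputs.
#'
#' @param config a [pipeline_config()]
#' @return invisible list with the in-memory results and `files`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "pipeline.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  logf("panelgwas pipeline, seed=%d", config$seed)

  # stage: inputs
  truth <- NULL
  if (isTRUE(config$simulate)) {
    stage("simulate", {
      cfg <- config$sim_config
      cfg$seed <- stream_seed(config$seed, 1)
      G <- simulate_genotypes(cfg)
      truth <- default_truth(G)
      recs <- simulate_traits(G, truth, seed = stream_seed(config$seed, 2))
      write_hapmap(G, fp <- file.path(config$outdir, "genotypes.hmp.txt"))
      files <- c(files, fp)
      write_truth(truth, fp <- file.path(config$outdir, "truth.json"))
      files <- c(files, fp)
      write_phenotypes(recs, fp <- file.path(config$outdir, "phenotypes.tsv"),
                       seed = config$seed)
      files <- c(files, fp)
    })
  } else {
    stage("read", {
      G <- if (grepl("\\.vcf$", config$genotypes, ignore.case = TRUE))
        read_vcf(config$genotypes) else read_hapmap(config$genotypes)
      recs <- read_phenotypes(config$phenotypes)
    })
  }
  logf("inputs: %d accessions, %d SNPs, %d phenotype records",
       nrow(G$dosages), ncol(G$dosages), nrow(recs))
  halt <- function(at) identical(config$stop_after %||% "all", at)
  if (halt("simulate"))
    return(invisible(list(genotypes = G, phenotypes = recs, truth = truth,
                          files = files)))

  # stage: phenotype statistics
  stage("pheno", {
    tm <- trait_matrix(recs, traits = config$traits)
    write_trait_matrix(tm, fp <- file.path(config$outdir, "trait_matrix.tsv"))
    files <- c(files, fp)
    cors <- correlation_matrix(tm)
    utils::write.table(round(cors$r, 4),
                       fp <- file.path(config$outdir, "correlations.tsv"),
                       sep = "\t", quote = FALSE)
    files <- c(files, fp)
  })
  traits <- colnames(tm)
  if (halt("pheno"))
    return(invisible(list(genotypes = G, phenotypes = recs,
                          trait_matrix = tm, truth = truth, files = files)))

  if (isTRUE(config$bn_only)) {
    # network-only route: skip association and region stages
    dag <- NULL
    stage("bn", {
      bl <- stage_blacklist(default_stages(colnames(tm)))
      cfgbn <- config$bn
      cfgbn$seed <- stream_seed(config$seed, 3)
      cfgbn$validation_size <- min(cfgbn$validation_size,
                                   max(2, nrow(tm) %/% 5))
      dag <- cv_learn(tm, cfgbn, blacklist = bl)
      paths <- write_dag(dag, file.path(config$outdir, "trait_dag.tsv"))
      files <- c(files, paths)
    })
    logf("pipeline complete (bn only): %d output files", length(files))
    return(invisible(list(genotypes = G, phenotypes = recs,
                          trait_matrix = tm, truth = truth, dag = dag,
                          files = files)))
  }

  # stage: panels + gwas
  panels <- config$panels
  if (is.null(panels)) {
    panels <- if (!is.null(G$subpop))
      default_panels(G$subpop, G$admix_parents)
    else list(All = panel_def("All", rownames(G$dosages), 3))
  }
  scans <- list()
  stage("gwas", {
    full_st <- allele_stats_matrix(G$dosages, G$map)
    ref_common <- stats::setNames(full_st$common_allele, G$map$snp)
    for (pn in names(panels)) {
      pd <- panels[[pn]]
      if (length(pd$members) < 10) next  # too small to scan
      Gp <- subset_panel(G, pd, min_alt_carriers = config$min_alt_carriers)
      K <- centered_kinship(Gp)
      pcs <- genotype_pca(Gp, pd$n_pcs)
      for (t in traits) {
        a <- mlm_scan(Gp, tm[, t], K, covariates = pcs, trait = t, panel = pn)
        scans[[paste(t, pn, sep = ".")]] <- a
      }
    }
    for (nm in names(scans)) {
      fp <- file.path(config$outdir, sprintf("assoc_%s.tsv", nm))
      write_tsv_prov(format_assoc(scans[[nm]]), fp, seed = config$seed)
      files <- c(files, fp)
    }
  })

  if (halt("gwas"))
    return(invisible(list(genotypes = G, phenotypes = recs,
                          trait_matrix = tm, truth = truth, scans = scans,
                          files = files)))

  # stage: regions + coloc + pivot
  stage("regions", {
    qtls_by_trait <- list()
    for (t in traits) {
      al <- scans[grepl(paste0("^", t, "\\."), names(scans))]
      qtls_by_trait[[t]] <- call_qtl(al, threshold = config$sig,
                                     extend = config$extend,
                                     flank = config$flank,
                                     merge_gap = config$merge_gap,
                                     min_snps = config$min_snps,
                                     min_alt_carriers = config$min_alt_carriers,
                                     ref_common = ref_common,
                                     trait_symbol = t)
    }
    pairs <- utils::combn(traits, 2, simplify = FALSE)
    colocs <- do.call(rbind, lapply(pairs, function(p)
      coloc(qtls_by_trait[[p[1]]], qtls_by_trait[[p[2]]],
            end_gap = config$coloc_gap)))
    if (is.null(colocs))
      colocs <- data.frame(qtl_a = character(), qtl_b = character(),
                           basis = character(), gap = numeric())
    all_qtls <- unlist(qtls_by_trait, recursive = FALSE)
    paths <- write_qtl_report(all_qtls, colocs,
                              file.path(config$outdir, "qtl_report.tsv"),
                              seed = config$seed)
    files <- c(files, paths)
    write_tsv_prov(colocs, fp <- file.path(config$outdir, "coloc.tsv"),
                   seed = config$seed)
    files <- c(files, fp)
    pivots <- list()
    for (t in names(qtls_by_trait)) for (q in qtls_by_trait[[t]]) {
      if (!isTRUE(q$claimed)) next
      pv <- pivot_allele_effects(q$peak, G, tm)
      pv$qtl <- q$name
      pivots[[length(pivots) + 1]] <- pv
    }
    if (length(pivots)) {
      write_tsv_prov(do.call(rbind, pivots),
                     fp <- file.path(config$outdir, "pivot.tsv"),
                     seed = config$seed)
      files <- c(files, fp)
    }
  })

  if (halt("regions"))
    return(invisible(list(genotypes = G, phenotypes = recs,
                          trait_matrix = tm, truth = truth, scans = scans,
                          qtls = qtls_by_trait, colocs = colocs,
                          files = files)))

  # stage: gene annotation (optional)
  genes <- NULL
  if (isTRUE(config$run_annotate) && !is.null(config$annotations)) {
    stage("annotate", {
      ann <- read_gene_annotations(config$annotations)
      genes <- genes_near(unlist(qtls_by_trait, recursive = FALSE), ann,
                          window = config$gene_window)
      write_tsv_prov(genes, fp <- file.path(config$outdir,
                                            "candidate_genes.tsv"),
                     seed = config$seed)
      files <- c(files, fp)
    })
  } else if (isTRUE(config$run_annotate)) {
    logf("annotate stage skipped: no annotation path given")
  }

  # stage: trait network
  dag <- NULL
  if (isTRUE(config$run_bn)) {
    stage("bn", {
      bl <- stage_blacklist(default_stages(colnames(tm)))
      cfgbn <- config$bn
      cfgbn$seed <- stream_seed(config$seed, 3)
      cfgbn$validation_size <- min(cfgbn$validation_size,
                                   max(2, nrow(tm) %/% 5))
      dag <- cv_learn(tm, cfgbn, blacklist = bl)
      paths <- write_dag(dag, file.path(config$outdir, "trait_dag.tsv"))
      files <- c(files, paths)
    })
  }
  logf("pipeline complete: %d output files", length(files))
  invisible(list(genotypes = G, phenotypes = recs, trait_matrix = tm,
                 truth = truth, scans = scans, qtls = qtls_by_trait,
                 colocs = colocs, genes = genes, dag = dag, files = files))
}

# fixed-width numeric formatting so reruns are byte-identical across
# platforms
format_assoc <- function(a) {
  a$minus_log10_p <- sprintf("%.6f", a$minus_log10_p)
  a$effect_common <- sprintf("%.6g", a$effect_common)
  a
}
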