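# End-to-end orchestration and annotation utilities.  Every stage writes a
# TSV artifact plus a JSON manifest so a run can be audited and replayed.

#' Build a run configuration
#'
#' @param genotypes path to a PLINK prefix or dosage TSV.
#' @param phenotypes path to the phenotype TSV (`accession_id` + traits).
#' @param out_dir output directory.
#' @param traits optional trait subset/order.
#' @param min_call_rate,min_maf QC thresholds (see [qc_filter()]).
#' @param mcmc an [mcmc_config()].
#' @param n_boot,strength_threshold bootstrap settings for structure
#'   learning.
#' @param top_k SNPs per trait carried into the SEM decomposition report.
#' @param snp_subset optional explicit SNP subset for SEM-GWAS (overrides
#'   `top_k`; `NULL` plus `top_k = Inf` scans all SNPs).
#' @param annotation optional GFF3 path for candidate-gene windows.
#' @param window_bp candidate-gene window half-width (default 200000).
#' @param seed master seed; propagated to every stochastic stage.
#' @return Object of class `run_config`.
#' @export
run_config <- function(genotypes, phenotypes, out_dir, traits = NULL,
                       min_call_rate = 0.95, min_maf = 0.05,
                       mcmc = mcmc_config(), n_boot = 2500,
                       strength_threshold = 0.85, top_k = 50,
                       snp_subset = NULL, annotation = NULL,
                       window_bp = 200000, seed = 1) {
  cfg <- structure(list(genotypes = genotypes, phenotypes = phenotypes,
                        out_dir = out_dir, traits = traits,
                        min_call_rate = min_call_rate, min_maf = min_maf,
                        mcmc = mcmc, n_boot = n_boot,
                        strength_threshold = strength_threshold,
                        top_k = top_k, snp_subset = snp_subset,
                        annotation = annotation, window_bp = window_bp,
                        seed = as.integer(seed)),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  geno_ok <- file.exists(cfg$genotypes) ||
    file.exists(paste0(cfg$genotypes, ".bed"))
  assert_that(geno_ok, paste0("genotype input not found: ", cfg$genotypes))
  assert_that(file.exists(cfg$phenotypes),
              paste0("phenotype file not found: ", cfg$phenotypes))
  if (!is.null(cfg$annotation)) {
    assert_that(file.exists(cfg$annotation),
                paste0("annotation file not found: ", cfg$annotation))
  }
  invisible(cfg)
}

# Minimal GFF3 gene-record parser.  A hand parser (rather than a full GFF3
# import) so malformed lines can be reported by number, which is the error
# contract callers rely on.
parse_gff3_genes <- function(path, feature_types = c("gene")) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  recs <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9) {
      stop2(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, got %d",
                    i, length(f)))
    }
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end)) {
      stop2(sprintf("malformed GFF3 line %d: non-integer coordinates", i))
    }
    if (!f[3] %in% feature_types) next
    id <- sub(".*ID=([^;]+).*", "\\1", f[9])
    if (id == f[9]) id <- sprintf("%s:%d-%d", f[1], start, end)
    recs[[length(recs) + 1]] <- data.frame(gene_id = id, chromosome = f[1],
                                           start = start, end = end,
                                           stringsAsFactors = FALSE)
  }
  if (!length(recs)) {
    return(data.frame(gene_id = character(0), chromosome = character(0),
                      start = integer(0), end = integer(0)))
  }
  do.call(rbind, recs)
}

#' Genes within a window of each SNP
#'
#' A gene is reported for a SNP when the gene interval overlaps
#' `[position - window_bp, position + window_bp]` (1-based inclusive on both
#' ends) on the same chromosome.
#'
#' @param snps data.frame with `snp_id`, `chromosome`, `position_bp` (e.g.
#'   the first three columns of an association table).
#' @param annotation path to a GFF3 file, or a pre-parsed data.frame with
#'   `gene_id`, `chromosome`, `start`, `end`.
#' @param window_bp half-width of the window in bp (default 200000).
#' @return data.frame `snp_id`, `gene_id`, `chromosome`, `start`, `end`,
#'   `distance_bp` (0 when the SNP lies inside the gene).
#' @export
candidate_gene_window <- function(snps, annotation, window_bp = 200000) {
  genes <- if (is.character(annotation)) parse_gff3_genes(annotation) else
    as.data.frame(annotation)
  out <- list()
  for (i in seq_len(nrow(snps))) {
    pos <- snps$position_bp[i]
    hit <- genes$chromosome == as.character(snps$chromosome[i]) &
      genes$start <= pos + window_bp & genes$end >= pos - window_bp
    if (!any(hit)) next
    gh <- genes[hit, , drop = FALSE]
    dist <- pmax(0, pmax(gh$start - pos, pos - gh$end))
    out[[length(out) + 1]] <- data.frame(snp_id = snps$snp_id[i], gh,
                                         distance_bp = dist,
                                         stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      chromosome = character(0), start = integer(0),
                      end = integer(0), distance_bp = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full pipeline
#'
#' Stages: read genotypes and phenotypes, QC filter, mean imputation, GRM,
#' MT-GBLUP, Bayesian-network structure learning on the genetic values
#' (bootstrap + model averaging + per-arc BIC), MTM-GWAS, SEM-GWAS
#' decomposition on the top SNPs, and (optionally) candidate-gene windows.
#' Each stage writes its TSV artifact under `cfg$out_dir`; a JSON manifest
#' records the configuration, seed and stage summaries. Re-running an
#' identical configuration reproduces identical outputs.
#'
#' @param cfg a [run_config()].
#' @return `cfg$out_dir`, invisibly.
#' @export
run_pipeline <- function(cfg) {
  validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    message(sprintf("[%s] ...", name))
    res <- tryCatch(force(expr), error = function(e) {
      stop2(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  geno <- stage("read", {
    g <- read_genotypes(cfg$genotypes)
    g <- qc_filter(g, cfg$min_call_rate, cfg$min_maf)
    impute_mean(g)
  })
  pheno <- stage("phenotypes", {
    ph <- read_phenotypes(cfg$phenotypes)
    if (!is.null(cfg$traits)) ph <- ph[, c("accession_id", cfg$traits)]
    ph
  })
  grm <- stage("grm", {
    grm <- compute_grm(center_markers(geno))
    gm <- data.frame(accession_id = grm$accession_ids, grm$matrix,
                     check.names = FALSE)
    data.table::fwrite(gm, file.path(cfg$out_dir, "grm.tsv"), sep = "\t")
    grm
  })
  mc <- cfg$mcmc
  mc$seed <- cfg$seed
  fit <- stage("mt_gblup", {
    fit <- fit_mt_gblup(pheno, grm, mc, traits = cfg$traits)
    write_gblup_outputs(fit, cfg$out_dir)
    fit
  })
  net <- stage("network", {
    strengths <- bootstrap_strength(fit$genetic_values, n_boot = cfg$n_boot,
                                    seed = cfg$seed)
    net <- averaged_network(strengths, cfg$strength_threshold)
    net <- arc_strength_delta_bic(fit$genetic_values, net)
    write_network(net, file.path(cfg$out_dir, "network.tsv"),
                  file.path(cfg$out_dir, "network.dot"))
    net
  })
  mtm <- stage("mtm_gwas", {
    mtm <- run_mtm_gwas(geno, pheno, grm, fit$components, traits = cfg$traits)
    data.table::fwrite(mtm, file.path(cfg$out_dir, "mtm_effects.tsv"),
                       sep = "\t")
    mtm
  })
  sem <- stage("sem_gwas", {
    subset_ids <- cfg$snp_subset
    if (is.null(subset_ids) && is.finite(cfg$top_k)) {
      subset_ids <- unique(unlist(lapply(fit$trait_names, function(tr) {
        rank_top_snps(mtm, tr, min(cfg$top_k, nrow(mtm)))$snp_id
      })))
    }
    sem <- run_sem_gwas(geno, pheno, net, grm, fit$components,
                        snp_subset = subset_ids, mtm = mtm)
    data.table::fwrite(sem, file.path(cfg$out_dir, "sem_decomposition.tsv"),
                       sep = "\t")
    lam <- attr(sem, "lambda")
    lam_df <- data.frame(child = rep(lam$traits, times = length(lam$traits)),
                         parent = rep(lam$traits, each = length(lam$traits)),
                         lambda = as.vector(lam$lambda),
                         se = as.vector(lam$std_errors))
    data.table::fwrite(lam_df[lam_df$lambda != 0, ],
                       file.path(cfg$out_dir, "lambda.tsv"), sep = "\t")
    sem
  })
  if (!is.null(cfg$annotation)) {
    stage("annotate", {
      hits <- candidate_gene_window(sem[, c("snp_id", "chromosome",
                                            "position_bp")],
                                    cfg$annotation, cfg$window_bp)
      data.table::fwrite(hits, file.path(cfg$out_dir, "candidate_genes.tsv"),
                         sep = "\t")
      hits
    })
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("semgwas")),
    seed = cfg$seed,
    config = list(genotypes = cfg$genotypes, phenotypes = cfg$phenotypes,
                  traits = cfg$traits %||% fit$trait_names,
                  min_call_rate = cfg$min_call_rate, min_maf = cfg$min_maf,
                  n_burnin = mc$n_burnin, n_iter = mc$n_iter, thin = mc$thin,
                  n_boot = cfg$n_boot,
                  strength_threshold = cfg$strength_threshold,
                  top_k = cfg$top_k, window_bp = cfg$window_bp),
    n_accessions = length(fit$accession_ids),
    n_snps = ncol(geno$dosages),
    network_arcs = paste(net$arcs$from, "->", net$arcs$to),
    heritabilities = as.list(genomic_heritabilities(fit)$mean),
    psrf = as.list(fit$psrf))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cfg$out_dir)
}
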