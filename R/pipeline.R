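#' Pipeline run configuration
#'
#' Collects every analysis threshold in one validated list. The defaults
#' are the canonical values of the underlying study design: detection
#' p-value 0.01 with 25\% (sample) and 50\% (probe) failure fractions, SNP
#' MAF 0.01, BH q 0.05, |mean beta difference| 0.2, unidirectional-DMP
#' region fraction 0.25, Spearman rho -0.5 with raw p 0.05, and kappa 0.4.
#'
#' @param detp_threshold detection p-value failure cutoff.
#' @param sample_frac_threshold failing-probe fraction that drops a sample.
#' @param probe_frac_threshold failing-sample fraction that drops a probe.
#' @param maf_threshold SNP minor-allele-frequency cutoff (strict).
#' @param q_threshold BH significance cutoff (DMP, DMR verification, DE).
#' @param delta_beta_threshold minimum |mean beta difference| for a DMP.
#' @param dmr_fraction unidirectional-DMP fraction for a region call.
#' @param rho_threshold Spearman correlation cutoff (strict less-than).
#' @param rho_p_threshold raw p cutoff for the correlation flag.
#' @param kappa_threshold term-grouping kappa cutoff (inclusive).
#' @param fpkm_expressed FPKM floor for counting a gene as expressed.
#' @param n_top_variable probes used for misclassification clustering.
#' @param dmp_method \code{"wilcoxon"} or \code{"t_logit"}.
#' @param remove_flagged drop both members of flagged pairs (default TRUE).
#' @param qn_per_cohort quantile-normalize discovery and validation
#'   cohorts separately (default TRUE).
#' @param tumor_only_correlation restrict the correlation filter to tumor
#'   samples (default FALSE).
#' @param seed seed for the within-array normalization subsets.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(detp_threshold = 0.01, sample_frac_threshold = 0.25,
                       probe_frac_threshold = 0.5, maf_threshold = 0.01,
                       q_threshold = 0.05, delta_beta_threshold = 0.2,
                       dmr_fraction = 0.25, rho_threshold = -0.5,
                       rho_p_threshold = 0.05, kappa_threshold = 0.4,
                       fpkm_expressed = 0.1, n_top_variable = 1000,
                       dmp_method = "wilcoxon", remove_flagged = TRUE,
                       qn_per_cohort = TRUE,
                       tumor_only_correlation = FALSE, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$detp_threshold > 0, cfg$q_threshold > 0,
            cfg$dmr_fraction > 0, cfg$kappa_threshold >= -1,
            cfg$dmp_method %in% c("wilcoxon", "t_logit"))
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Reads threshold overrides from YAML and merges them over the
#' \code{\link{run_config}} defaults; unknown keys are rejected.
#'
#' @param path YAML file with any subset of \code{run_config} fields.
#' @return a \code{run_config}.
#' @export
run_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configurations")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  }
  do.call(run_config, vals)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full methylation/expression integration pipeline
#'
#' Executes the nine analysis stages in fixed order — quality control,
#' normalization, DMP calling, DMR calling, region-level verification,
#' differential expression, epigenetic integration, gene-set enrichment,
#' and TF-network ranking — writing each stage's tables under
#' \code{out_dir} and a \code{manifest.json} recording stage parameters,
#' outputs and file checksums. Downstream stages of an empty result (e.g.
#' no DMPs under a strict threshold) emit empty-but-valid tables.
#'
#' @param dataset a dataset list from \code{\link{generate_dataset}} /
#'   \code{\link{read_dataset}}, or a directory path to read.
#' @param out_dir output directory.
#' @param config a \code{\link{run_config}}.
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(dataset, out_dir, config = run_config()) {
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  manifest <- list()
  note <- function(stage, params, outputs) {
    manifest[[stage]] <<- list(params = params, outputs = outputs)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## 1. qc ------------------------------------------------------------------
  qc <- run_stage("qc", {
    sdrop <- drop_failed_samples(dataset$detection_p,
                                 config$sample_frac_threshold,
                                 config$detp_threshold)
    pdrop <- filter_probes(dataset$annotation,
                           dataset$detection_p[, sdrop$kept, drop = FALSE],
                           config$probe_frac_threshold,
                           config$detp_threshold, config$maf_threshold)
    beta_raw <- compute_beta(
      dataset$M[pdrop$kept, sdrop$kept, drop = FALSE],
      dataset$U[pdrop$kept, sdrop$kept, drop = FALSE])
    sheet <- dataset$sample_sheet[
      dataset$sample_sheet$sample_id %in% sdrop$kept, , drop = FALSE]
    flags <- detect_misclassified_pairs(beta_raw, sheet,
                                        config$n_top_variable)
    if (config$remove_flagged && length(flags$flagged_patients) > 0) {
      sheet <- sheet[!(sheet$patient_id %in% flags$flagged_patients), ,
                     drop = FALSE]
    }
    report <- list(
      dropped_samples = sdrop$dropped, dropped_probes = pdrop$dropped,
      flagged_pairs = flags$flagged_patients,
      flagged_samples = flags$flagged_samples,
      n_probes_kept = length(pdrop$kept),
      n_samples_kept = nrow(sheet)
    )
    jsonlite::write_json(report, fp("qc_report.json"), auto_unbox = FALSE,
                         digits = NA, pretty = TRUE)
    list(kept_probes = pdrop$kept, sheet = sheet, report = report)
  })
  note("qc",
       list(detp = config$detp_threshold,
            sample_frac = config$sample_frac_threshold,
            probe_frac = config$probe_frac_threshold,
            maf = config$maf_threshold,
            remove_flagged = config$remove_flagged),
       "qc_report.json")
  keep_samples <- qc$sheet$sample_id

  ## 2. normalize -----------------------------------------------------------
  beta <- run_stage("normalize", {
    sw <- swan_normalize(
      dataset$M[qc$kept_probes, keep_samples, drop = FALSE],
      dataset$U[qc$kept_probes, keep_samples, drop = FALSE],
      dataset$annotation, seed = config$seed)
    b <- compute_beta(sw$M, sw$U)
    if (config$qn_per_cohort && "cohort" %in% names(qc$sheet)) {
      for (co in unique(qc$sheet$cohort)) {
        ids <- qc$sheet$sample_id[qc$sheet$cohort == co]
        b[, ids] <- suppressWarnings(
          quantile_normalize_beta(b[, ids, drop = FALSE]))
      }
      b
    } else {
      quantile_normalize_beta(b)
    }
  })
  run_stage("normalize", {
    .write_matrix_tsv(beta, fp("beta_normalized.tsv"), "probe_id")
  })
  note("normalize", list(seed = config$seed,
                         qn_per_cohort = config$qn_per_cohort),
       "beta_normalized.tsv")

  ## 3. dmp -----------------------------------------------------------------
  dmps <- run_stage("dmp", {
    out <- call_dmps(beta, qc$sheet, config$q_threshold,
                     config$delta_beta_threshold, config$dmp_method)
    .write_tsv(out, fp("dmp.tsv"))
    out
  })
  note("dmp", list(q = config$q_threshold,
                   delta_beta = config$delta_beta_threshold,
                   method = config$dmp_method),
       "dmp.tsv")

  ## 4. dmr -----------------------------------------------------------------
  index <- build_region_index(dataset$annotation, qc$kept_probes)
  dmrs <- run_stage("dmr", {
    out <- call_dmrs(dmps, index, beta, qc$sheet, config$dmr_fraction)
    .write_tsv(out$dmrs, fp("dmr.tsv"))
    .write_tsv(out$full, fp("dmr_full.tsv"))
    cgi <- summarize_cgi_distribution(dmps, dataset$annotation)
    .write_tsv(cgi, fp("cgi_summary.tsv"))
    out
  })
  note("dmr", list(fraction = config$dmr_fraction),
       c("dmr.tsv", "dmr_full.tsv", "cgi_summary.tsv"))

  ## 5. verify --------------------------------------------------------------
  verification <- run_stage("verify", {
    out <- verify_dmrs_regionwise(beta, index, qc$sheet,
                                  config$q_threshold)
    out$overlap <- NULL
    .write_tsv(out, fp("verification.tsv"))
    out
  })
  overlap <- verification_overlap(dmrs$dmrs, verification)
  note("verify", list(q = config$q_threshold, overlap = overlap),
       "verification.tsv")

  ## 6. de ------------------------------------------------------------------
  degs <- run_stage("de", {
    out <- call_degs(dataset$expression, qc$sheet, config$q_threshold)
    .write_tsv(out, fp("degs.tsv"))
    out
  })
  note("de", list(q = config$q_threshold), "degs.tsv")

  ## 7. integrate -----------------------------------------------------------
  integration <- run_stage("integrate", {
    prom <- dmrs$full[dmrs$full$region_group == "promoter", , drop = FALSE]
    epi <- classify_epigenetic_genes(prom, degs)
    if (nrow(epi) > 0) {
      corr <- correlate_promoter_expression(
        beta, index, dataset$expression, qc$sheet, epi$gene, dmps,
        config$rho_threshold, config$rho_p_threshold,
        config$tumor_only_correlation)
      epi <- merge(epi, corr, by = "gene")
      epi <- epi[order(epi$gene), ]
    } else {
      epi$n_samples <- integer(0); epi$rho <- numeric(0)
      epi$p <- numeric(0); epi$significantly_correlated <- logical(0)
    }
    .write_tsv(epi, fp("epigenes.tsv"))
    writeLines(epi$gene[epi$epi_class == "silenced"], fp("silenced.txt"))
    writeLines(epi$gene[epi$epi_class == "overexpressed"],
               fp("overexpressed.txt"))
    epi
  })
  note("integrate", list(rho = config$rho_threshold,
                         rho_p = config$rho_p_threshold),
       c("epigenes.tsv", "silenced.txt", "overexpressed.txt"))

  ## 8. enrich --------------------------------------------------------------
  enrichment <- run_stage("enrich", {
    query <- integration$gene
    if (length(query) == 0) {
      res <- data.frame(term_id = character(0), set_size = integer(0),
                        overlap_count = integer(0),
                        overlap_genes = character(0),
                        p_two_sided = numeric(0), p_corrected = numeric(0),
                        significant = logical(0), stringsAsFactors = FALSE)
      groups <- cbind(res, data.frame(group_id = integer(0),
                                      is_group_leader = logical(0)))
    } else {
      res <- hypergeometric_enrich(query, dataset$geneset_library,
                                   rownames(dataset$expression))
      groups <- kappa_group_terms(res, config$kappa_threshold)
    }
    .write_tsv(res, fp("enrichment.tsv"))
    .write_tsv(groups, fp("groups.tsv"))
    list(results = res, groups = groups)
  })
  note("enrich", list(kappa = config$kappa_threshold),
       c("enrichment.tsv", "groups.tsv"))

  ## 9. tfnet ---------------------------------------------------------------
  tfnet <- run_stage("tfnet", {
    query <- integration$gene
    if (length(query) == 0) {
      network <- list(
        edges = data.frame(source = character(0), target = character(0),
                           interaction = character(0)),
        nodes = data.frame(id = character(0), role = character(0),
                           in_query = logical(0),
                           epi_class = character(0)),
        out_degree = stats::setNames(integer(0), character(0)))
      ranking <- rank_tfs_by_outdegree(network)
    } else {
      status <- stats::setNames(integration$epi_class, integration$gene)
      network <- build_tf_network(dataset$tf_library, query, status)
      ranking <- rank_tfs_by_outdegree(network)
    }
    .write_tsv(network$edges, fp("network_edges.tsv"))
    .write_tsv(ranking, fp("tf_ranking.tsv"))
    list(network = network, ranking = ranking)
  })
  note("tfnet", list(), c("network_edges.tsv", "tf_ranking.tsv"))

  ## manifest ---------------------------------------------------------------
  all_files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  sums <- tools::md5sum(file.path(out_dir, all_files))
  manifest_out <- list(
    stages = manifest,
    n_stages = length(manifest),
    checksums = as.list(stats::setNames(unname(sums), all_files))
  )
  jsonlite::write_json(manifest_out, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(qc = qc$report, beta = beta, dmps = dmps, dmrs = dmrs,
                 verification = verification, overlap = overlap,
                 degs = degs, epigenes = integration,
                 enrichment = enrichment, tfnet = tfnet,
                 manifest = manifest_out))
}
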