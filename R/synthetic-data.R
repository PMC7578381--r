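#' Configuration for the paired tumor/normal synthetic dataset
#'
#' Defines the planted study conditions: cohort sizes, array content,
#' methylation and expression effect sizes, noise levels, and the
#' quality-control violations, label swaps and network hubs planted for
#' downstream recovery. All randomness is governed by \code{seed}; a fixed
#' seed yields byte-identical output.
#'
#' @param n_pairs patients with a complete tumor/adjacent-normal pair
#'   (default 14).
#' @param n_validation_tumors unpaired tumors in the validation cohort
#'   (default 10).
#' @param n_probes total array probes (default 6000).
#' @param n_genes total genes (default 300); each gene receives 1-3 probes
#'   per manifest sub-region.
#' @param frac_hyper_dmp,frac_hypo_dmp target fractions of probes carrying
#'   planted hyper-/hypomethylation effects (defaults 0.05 / 0.03); the
#'   promoter probes of planted epigenetically regulated genes count
#'   towards these totals.
#' @param delta_beta_effect planted mean beta shift in tumor (default 0.3).
#' @param beta_noise_sd within-group beta dispersion on the logit scale
#'   (default 0.25, roughly 0.05 on the beta scale at mid-range beta).
#' @param n_silenced,n_overexpressed planted epigenetically regulated gene
#'   counts (defaults 40 / 60).
#' @param expr_fold multiplicative tumor expression effect for planted
#'   genes (default 4).
#' @param expr_noise_sd sd of log2 FPKM noise (default 0.3).
#' @param coupling_sd sd of the shared per-gene-per-sample latent factor
#'   linking promoter methylation (+) and log2 expression (-) for planted
#'   genes (default 0.3); gives the correlation filter true positives.
#' @param n_swapped_pairs pairs whose tumor/normal labels are exchanged in
#'   the sample sheet only (default 2).
#' @param n_bad_samples samples given >= 25\% failed detection p-values
#'   (default 0; drawn from validation tumors first).
#' @param n_snp_probes,n_nonCpG_probes,n_sex_probes,n_na_probes,n_high_detp_probes
#'   planted per-rule probe-filter violations (defaults 50/30/20/10/40),
#'   pairwise disjoint and disjoint from planted effect probes.
#' @param type2_bias multiplicative intensity bias applied to both channels
#'   of Infinium type-II probes (default 1.5; 1 disables).
#' @param frac_type2 fraction of probes assigned design type II
#'   (default 0.72).
#' @param n_tfs transcription factors in the target library (default 93).
#' @param hub_degrees intended out-degrees of the planted hub TFs over the
#'   planted epigenetically regulated gene list (default c(81, 53, 48)).
#' @param n_genesets pathway gene sets in the second library (default 20).
#' @param seed integer RNG seed (default 1).
#' @return validated \code{sim_config} list.
#' @export
sim_config <- function(n_pairs = 14, n_validation_tumors = 10,
                       n_probes = 6000, n_genes = 300,
                       frac_hyper_dmp = 0.05, frac_hypo_dmp = 0.03,
                       delta_beta_effect = 0.3, beta_noise_sd = 0.25,
                       n_silenced = 40, n_overexpressed = 60,
                       expr_fold = 4, expr_noise_sd = 0.3,
                       coupling_sd = 0.3,
                       n_swapped_pairs = 2, n_bad_samples = 0,
                       n_snp_probes = 50, n_nonCpG_probes = 30,
                       n_sex_probes = 20, n_na_probes = 10,
                       n_high_detp_probes = 40,
                       type2_bias = 1.5, frac_type2 = 0.72,
                       n_tfs = 93, hub_degrees = c(81, 53, 48),
                       n_genesets = 20, seed = 1L) {
  cfg <- as.list(environment())
  for (f in c("frac_hyper_dmp", "frac_hypo_dmp", "frac_type2")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  counts <- c("n_pairs", "n_validation_tumors", "n_probes", "n_genes",
              "n_silenced", "n_overexpressed", "n_swapped_pairs",
              "n_bad_samples", "n_snp_probes", "n_nonCpG_probes",
              "n_sex_probes", "n_na_probes", "n_high_detp_probes",
              "n_tfs", "n_genesets")
  for (f in counts) {
    if (cfg[[f]] < 0 || cfg[[f]] != round(cfg[[f]])) {
      stop(f, " must be a non-negative integer")
    }
  }
  if (n_silenced + n_overexpressed > n_genes) {
    stop("n_silenced + n_overexpressed exceeds n_genes")
  }
  if (n_swapped_pairs > n_pairs) stop("n_swapped_pairs exceeds n_pairs")
  qc_total <- n_snp_probes + n_nonCpG_probes + n_sex_probes + n_na_probes +
    n_high_detp_probes
  # every gene draws at least one probe in each of the six sub-regions
  if (qc_total + 6 * n_genes > n_probes) {
    stop("n_probes too small for the planted QC violations and gene model")
  }
  if (length(hub_degrees) > n_tfs) stop("more hub_degrees than n_tfs")
  if (n_silenced + n_overexpressed > 0 &&
      length(hub_degrees) > 0 &&
      max(hub_degrees) > n_silenced + n_overexpressed) {
    stop("hub_degrees exceed the planted epigenetically regulated gene count")
  }
  if (delta_beta_effect < 0 || delta_beta_effect > 0.45) {
    stop("delta_beta_effect must be in [0, 0.45]")
  }
  structure(cfg, class = "sim_config")
}

# sample() that never falls into the 1:x convenience trap
.draw <- function(x, size) x[sample.int(length(x), size)]

#' Generate a paired tumor/normal methylation + expression dataset
#'
#' Produces methylated/unmethylated intensity matrices with detection
#' p-values, a manifest-style probe annotation, a sample sheet, an FPKM
#' expression matrix, TF-target and pathway GMT libraries, and ground-truth
#' tables for every planted feature. Beta values are simulated on the
#' logit scale and converted to intensity pairs so the analysis pipeline,
#' not the generator, applies the beta formula; the planted beta is
#' recovered exactly by \code{M/(M+U+100)} when the type-II bias is
#' disabled.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list: \code{M}, \code{U}, \code{detection_p} (probes x samples),
#'   \code{annotation}, \code{sample_sheet}, \code{expression} (genes x
#'   discovery samples), \code{tf_library}, \code{geneset_library},
#'   \code{truth}, \code{config}.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  cfg <- config

  ## ---- samples -----------------------------------------------------------
  patients <- sprintf("P%02d", seq_len(cfg$n_pairs))
  disc <- data.frame(
    sample_id = c(paste0(patients, "_T"), paste0(patients, "_N")),
    patient_id = rep(patients, 2),
    true_tissue = rep(c("tumor", "normal"), each = cfg$n_pairs),
    cohort = "discovery", stringsAsFactors = FALSE)
  vali <- if (cfg$n_validation_tumors > 0) data.frame(
    sample_id = sprintf("V%02d_T", seq_len(cfg$n_validation_tumors)),
    patient_id = sprintf("V%02d", seq_len(cfg$n_validation_tumors)),
    true_tissue = "tumor", cohort = "validation", stringsAsFactors = FALSE)
  else NULL
  samples <- rbind(disc, vali)
  swapped <- sort(.draw(patients, cfg$n_swapped_pairs))
  samples$tissue <- samples$true_tissue
  for (p in swapped) {
    rows <- which(samples$patient_id == p)
    samples$tissue[rows] <- rev(samples$tissue[rows])
  }
  sample_sheet <- samples[, c("sample_id", "patient_id", "tissue", "cohort")]

  ## ---- probe layout ------------------------------------------------------
  genes <- sprintf("G%03d", seq_len(cfg$n_genes))
  subregions <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR")
  per_region <- matrix(sample(1:3, cfg$n_genes * 6, replace = TRUE),
                       cfg$n_genes, 6, dimnames = list(genes, subregions))
  n_gene_probes <- sum(per_region)
  qc_counts <- c(detp_50pct = cfg$n_high_detp_probes,
                 na_masked = cfg$n_na_probes,
                 snp_10bp = cfg$n_snp_probes,
                 non_cpg = cfg$n_nonCpG_probes,
                 sex_chrom = cfg$n_sex_probes)
  if (n_gene_probes + sum(qc_counts) > cfg$n_probes) {
    stop("n_probes too small for the drawn gene model; increase n_probes")
  }
  probe_ids <- sprintf("cg%06d", seq_len(cfg$n_probes))
  gene_idx <- seq_len(n_gene_probes)
  qc_idx <- split(
    n_gene_probes + seq_len(sum(qc_counts)),
    rep(names(qc_counts), qc_counts)
  )[names(qc_counts)[qc_counts > 0]]

  gene_map <- data.frame(
    probe = gene_idx,
    gene = rep(rep(genes, 6), as.vector(per_region)),
    region = rep(rep(subregions, each = cfg$n_genes), as.vector(per_region)),
    stringsAsFactors = FALSE)
  promoter_regions <- c("TSS1500", "TSS200", "5UTR")

  ## per-probe attributes
  chrom <- as.character(sample(1:22, cfg$n_probes, replace = TRUE))
  if (!is.null(qc_idx$sex_chrom)) {
    chrom[qc_idx$sex_chrom] <- sample(c("X", "Y"), qc_counts["sex_chrom"],
                                      replace = TRUE)
  }
  pos <- sample.int(1e8, cfg$n_probes, replace = TRUE)
  design_type <- ifelse(stats::runif(cfg$n_probes) < cfg$frac_type2,
                        "II", "I")
  probe_class <- rep("cg", cfg$n_probes)
  if (!is.null(qc_idx$non_cpg)) {
    half <- length(qc_idx$non_cpg) %/% 2
    probe_class[qc_idx$non_cpg] <-
      c(rep("ch", length(qc_idx$non_cpg) - half), rep("rs", half))
  }
  snp_within_10bp <- integer(cfg$n_probes)
  snp_maf <- numeric(cfg$n_probes)
  if (!is.null(qc_idx$snp_10bp)) {
    snp_within_10bp[qc_idx$snp_10bp] <- 1L
    snp_maf[qc_idx$snp_10bp] <- stats::runif(qc_counts["snp_10bp"], 0.02, 0.5)
  }
  masked <- integer(cfg$n_probes)
  if (!is.null(qc_idx$na_masked)) masked[qc_idx$na_masked] <- 1L
  n_cpgs <- sample(1:4, cfg$n_probes, replace = TRUE,
                   prob = c(0.4, 0.3, 0.2, 0.1))
  is_prom <- seq_len(cfg$n_probes) %in%
    gene_map$probe[gene_map$region %in% promoter_regions]
  cgi <- character(cfg$n_probes)
  cgi[is_prom] <- sample(
    c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea"),
    sum(is_prom), replace = TRUE,
    prob = c(0.70, 0.075, 0.075, 0.05, 0.05, 0.05))
  cgi[!is_prom] <- sample(
    c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea"),
    sum(!is_prom), replace = TRUE,
    prob = c(0.10, 0.05, 0.05, 0.05, 0.05, 0.70))

  ## ---- planted effects ---------------------------------------------------
  epi_pool <- .draw(genes, cfg$n_silenced + cfg$n_overexpressed)
  silenced <- sort(epi_pool[seq_len(cfg$n_silenced)])
  overexpressed <- sort(setdiff(epi_pool, silenced))
  prom_probes_of <- function(gs) {
    gene_map$probe[gene_map$gene %in% gs &
                     gene_map$region %in% promoter_regions]
  }
  hyper <- sort(unique(prom_probes_of(silenced)))
  hypo <- sort(unique(prom_probes_of(overexpressed)))
  qc_all <- unlist(qc_idx, use.names = FALSE)
  eligible <- setdiff(seq_len(cfg$n_probes), c(hyper, hypo, qc_all))
  extra_hyper <- max(0, round(cfg$frac_hyper_dmp * cfg$n_probes) -
                       length(hyper))
  extra_hypo <- max(0, round(cfg$frac_hypo_dmp * cfg$n_probes) -
                      length(hypo))
  add_h <- .draw(eligible, min(extra_hyper, length(eligible)))
  eligible <- setdiff(eligible, add_h)
  add_l <- .draw(eligible, min(extra_hypo, length(eligible)))
  hyper <- sort(c(hyper, add_h))
  hypo <- sort(c(hypo, add_l))

  baseline <- numeric(cfg$n_probes)
  rest <- setdiff(seq_len(cfg$n_probes), c(hyper, hypo))
  mode <- sample(1:3, length(rest), replace = TRUE, prob = c(0.5, 0.3, 0.2))
  baseline[rest] <- ifelse(mode == 1, stats::runif(length(rest), 0.05, 0.30),
                           ifelse(mode == 2,
                                  stats::runif(length(rest), 0.65, 0.88),
                                  stats::runif(length(rest), 0.30, 0.65)))
  baseline[hyper] <- stats::runif(length(hyper), 0.20, 0.50)
  baseline[hypo] <- stats::runif(length(hypo), 0.50, 0.80)
  tumor_level <- baseline
  tumor_level[hyper] <- baseline[hyper] + cfg$delta_beta_effect
  tumor_level[hypo] <- baseline[hypo] - cfg$delta_beta_effect

  n_samp <- nrow(samples)
  beta_true <- matrix(rep(baseline, n_samp), ncol = n_samp,
                      dimnames = list(probe_ids, samples$sample_id))
  tumor_cols <- samples$true_tissue == "tumor"
  beta_true[, tumor_cols] <- tumor_level

  ## latent factor coupling promoter methylation and expression of planted
  ## epigenetically regulated genes (per gene, per discovery sample)
  disc_ids <- disc$sample_id
  z <- matrix(stats::rnorm(length(epi_pool) * length(disc_ids)),
              length(epi_pool), length(disc_ids),
              dimnames = list(sort(epi_pool), disc_ids))

  noisy <- cfg$beta_noise_sd > 0 || cfg$coupling_sd > 0
  if (noisy) {
    lg <- stats::qlogis(pmin(pmax(beta_true, 1e-4), 1 - 1e-4))
    lg <- lg + matrix(stats::rnorm(length(lg), 0, cfg$beta_noise_sd),
                      nrow(lg))
    if (cfg$coupling_sd > 0) {
      for (g in rownames(z)) {
        pr <- unique(prom_probes_of(g))
        lg[pr, disc_ids] <- lg[pr, disc_ids] +
          cfg$coupling_sd * matrix(rep(z[g, ], each = length(pr)),
                                   length(pr))
      }
    }
    beta_obs <- stats::plogis(lg)
  } else {
    beta_obs <- beta_true
  }
  beta_obs <- pmin(pmax(beta_obs, 1e-3), 0.9)

  ## ---- intensities and detection p --------------------------------------
  total <- matrix(pmax(stats::rlnorm(cfg$n_probes * n_samp,
                                     log(4000), 0.25), 1200),
                  cfg$n_probes, n_samp)
  M <- beta_obs * (total + 100)
  U <- total - M
  dimnames(M) <- dimnames(U) <- dimnames(beta_true)
  if (cfg$type2_bias != 1) {
    t2 <- design_type == "II"
    M[t2, ] <- M[t2, ] * cfg$type2_bias
    U[t2, ] <- U[t2, ] * cfg$type2_bias
  }

  detp <- matrix(stats::runif(cfg$n_probes * n_samp, 0, 0.005),
                 cfg$n_probes, n_samp, dimnames = dimnames(beta_true))
  if (!is.null(qc_idx$detp_50pct)) {
    detp[qc_idx$detp_50pct, ] <-
      stats::runif(length(qc_idx$detp_50pct) * n_samp, 0.01, 1)
  }
  shuffle <- function(x) .draw(x, length(x))
  bad_pool <- c(if (!is.null(vali)) shuffle(vali$sample_id),
                shuffle(disc$sample_id[disc$true_tissue == "normal"]),
                shuffle(disc$sample_id[disc$true_tissue == "tumor"]))
  failing_samples <- utils::head(bad_pool, cfg$n_bad_samples)
  for (s in failing_samples) {
    fail_rows <- .draw(seq_len(cfg$n_probes),
                       ceiling(0.3 * cfg$n_probes))
    detp[fail_rows, s] <- stats::runif(length(fail_rows), 0.01, 1)
  }

  ## ---- annotation table --------------------------------------------------
  per_probe <- data.frame(
    probe_id = probe_ids, chrom = chrom, pos = pos,
    design_type = design_type, cgi_relation = cgi,
    probe_class = probe_class, snp_within_10bp = snp_within_10bp,
    snp_maf = snp_maf, masked = masked, n_cpgs_in_probe = n_cpgs,
    stringsAsFactors = FALSE)
  ann_gene <- per_probe[gene_map$probe, , drop = FALSE]
  ann_gene$gene <- gene_map$gene
  ann_gene$region <- gene_map$region
  others <- setdiff(seq_len(cfg$n_probes), unique(gene_map$probe))
  ann_other <- per_probe[others, , drop = FALSE]
  ann_other$gene <- ""
  ann_other$region <- ""
  annotation <- rbind(ann_gene, ann_other)
  annotation <- annotation[order(match(annotation$probe_id, probe_ids)), ]
  rownames(annotation) <- NULL

  ## ---- expression --------------------------------------------------------
  base_log2 <- stats::runif(cfg$n_genes, 0.5, 8)
  names(base_log2) <- genes
  expr_log2 <- matrix(rep(base_log2, length(disc_ids)),
                      ncol = length(disc_ids),
                      dimnames = list(genes, disc_ids))
  disc_tumor <- disc_ids[disc$true_tissue == "tumor"]
  expr_log2[silenced, disc_tumor] <-
    expr_log2[silenced, disc_tumor] - log2(cfg$expr_fold)
  expr_log2[overexpressed, disc_tumor] <-
    expr_log2[overexpressed, disc_tumor] + log2(cfg$expr_fold)
  if (cfg$expr_noise_sd > 0) {
    expr_log2 <- expr_log2 +
      matrix(stats::rnorm(length(expr_log2), 0, cfg$expr_noise_sd),
             nrow(expr_log2))
  }
  if (cfg$coupling_sd > 0) {
    expr_log2[rownames(z), ] <- expr_log2[rownames(z), ] -
      cfg$coupling_sd * z
  }
  expression <- 2^expr_log2

  ## ---- libraries ---------------------------------------------------------
  epi_all <- c(silenced, overexpressed)
  hub_ids <- character(length(cfg$hub_degrees))
  if (length(cfg$hub_degrees) > 0) {
    # mirror a ranking in which the 1st and 3rd hubs are themselves
    # epigenetically regulated
    hub_ids[1] <- silenced[1]
    if (length(hub_ids) >= 2) hub_ids[2] <- "TFHUB02"
    if (length(hub_ids) >= 3) hub_ids[3] <- overexpressed[1]
    if (length(hub_ids) > 3) {
      hub_ids[4:length(hub_ids)] <-
        sprintf("TFHUB%02d", 4:length(hub_ids))
    }
  }
  tf_library <- list()
  for (i in seq_along(cfg$hub_degrees)) {
    targets <- .draw(setdiff(epi_all, hub_ids[i]), cfg$hub_degrees[i])
    decoys <- .draw(setdiff(genes, c(epi_all, targets)),
                    min(20, length(setdiff(genes, c(epi_all, targets)))))
    tf_library[[hub_ids[i]]] <- sort(c(targets, decoys))
  }
  n_plain <- cfg$n_tfs - length(cfg$hub_degrees)
  for (i in seq_len(n_plain)) {
    id <- sprintf("TF%03d", i)
    tf_library[[id]] <- sort(.draw(genes, sample(5:15, 1)))
  }
  geneset_library <- list()
  n_enriched <- min(5, cfg$n_genesets)
  shared <- .draw(silenced, min(8, length(silenced)))
  for (i in seq_len(n_enriched)) {
    id <- sprintf("GS%02d", i)
    core <- if (i <= 2 && length(shared) > 0) shared
      else .draw(epi_all, min(10, length(epi_all)))
    fill <- .draw(setdiff(genes, core), 5)
    geneset_library[[id]] <- sort(unique(c(core, fill)))
  }
  for (i in seq_len(max(0, cfg$n_genesets - n_enriched))) {
    id <- sprintf("GS%02d", n_enriched + i)
    geneset_library[[id]] <- sort(.draw(genes, sample(10:30, 1)))
  }

  ## ---- truth tables ------------------------------------------------------
  dmp_status <- rep("null", cfg$n_probes)
  dmp_status[hyper] <- "hyper"
  dmp_status[hypo] <- "hypo"
  group_map <- c(TSS1500 = "promoter", TSS200 = "promoter",
                 `5UTR` = "promoter", `1stExon` = "body", Body = "body",
                 `3UTR` = "3UTR")
  gm <- unique(data.frame(gene = gene_map$gene,
                          region_group = unname(group_map[gene_map$region]),
                          probe = gene_map$probe,
                          stringsAsFactors = FALSE))
  gkey <- paste(gm$gene, gm$region_group, sep = "\r")
  np <- tapply(gm$probe, gkey, length)
  nh <- tapply(dmp_status[gm$probe] == "hyper", gkey, sum)
  nl <- tapply(dmp_status[gm$probe] == "hypo", gkey, sum)
  parts <- strsplit(names(np), "\r", fixed = TRUE)
  dmr_truth <- data.frame(
    gene = vapply(parts, `[`, "", 1),
    region_group = vapply(parts, `[`, "", 2),
    n_probes = as.integer(np), n_hyper = as.integer(nh),
    n_hypo = as.integer(nl),
    direction = dmr_direction(as.integer(np), as.integer(nh),
                              as.integer(nl)),
    stringsAsFactors = FALSE)
  dmr_truth <- dmr_truth[order(dmr_truth$gene, dmr_truth$region_group), ]
  rownames(dmr_truth) <- NULL

  truth <- list(
    dmp_truth = data.frame(probe_id = probe_ids, status = dmp_status,
                           stringsAsFactors = FALSE),
    dmr_truth = dmr_truth,
    epigene_truth = data.frame(
      gene = c(silenced, overexpressed),
      class = rep(c("silenced", "overexpressed"),
                  c(length(silenced), length(overexpressed))),
      stringsAsFactors = FALSE),
    swapped_pairs = swapped,
    failing_samples = failing_samples,
    failing_probes_by_rule = lapply(qc_idx, function(i) probe_ids[i]),
    hub_tfs = data.frame(tf = hub_ids,
                         intended_degree = cfg$hub_degrees,
                         stringsAsFactors = FALSE),
    true_tissue = stats::setNames(samples$true_tissue, samples$sample_id)
  )

  list(M = M, U = U, detection_p = detp, annotation = annotation,
       sample_sheet = sample_sheet, expression = expression,
       tf_library = tf_library, geneset_library = geneset_library,
       truth = truth, config = cfg)
}

# full-precision numeric TSV writers: doubles rendered with 17 significant
# digits so write/read round-trips reproduce values exactly
.write_matrix_tsv <- function(x, path, id_col) {
  chr <- matrix(formatC(x, digits = 17, format = "g"), nrow(x))
  df <- data.frame(rownames(x), chr, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df) <- c(id_col, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write a generated dataset to disk
#'
#' Emits TSV matrices (intensities, detection p, expression), the TSV
#' annotation, a CSV sample sheet, GMT libraries, JSON truth tables and a
#' JSON manifest. Numeric matrices are written at full precision so a
#' round-trip read reproduces values exactly.
#'
#' @param dataset output of \code{\link{generate_dataset}}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  fp <- function(f) file.path(out_dir, f)
  .write_matrix_tsv(dataset$M, fp("intensity_m.tsv"), "probe_id")
  .write_matrix_tsv(dataset$U, fp("intensity_u.tsv"), "probe_id")
  .write_matrix_tsv(dataset$detection_p, fp("detection_p.tsv"), "probe_id")
  .write_matrix_tsv(dataset$expression, fp("expression.tsv"), "gene")
  ann <- dataset$annotation
  ann$snp_maf <- formatC(ann$snp_maf, digits = 17, format = "g")
  utils::write.table(ann, fp("annotation.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(dataset$sample_sheet, fp("samples.csv"),
                   row.names = FALSE, quote = FALSE)
  write_gmt(dataset$tf_library, fp("tf_targets.gmt"))
  write_gmt(dataset$geneset_library, fp("gene_sets.gmt"))
  jsonlite::write_json(dataset$truth, fp("truth.json"), auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  n_validation <- sum(dataset$sample_sheet$cohort == "validation")
  manifest <- list(
    files = c("intensity_m.tsv", "intensity_u.tsv", "detection_p.tsv",
              "expression.tsv", "annotation.tsv", "samples.csv",
              "tf_targets.gmt", "gene_sets.gmt", "truth.json"),
    n_probes = nrow(dataset$M), n_samples = ncol(dataset$M),
    n_genes = nrow(dataset$expression),
    n_validation_samples = n_validation,
    validation_cohort = if (n_validation > 0) "present" else "absent",
    seed = dataset$config$seed
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read a dataset previously written by \code{\link{write_dataset}}
#'
#' @param dir dataset directory.
#' @return list mirroring \code{\link{generate_dataset}} output (without
#'   \code{config}).
#' @export
read_dataset <- function(dir) {
  fp <- function(f) file.path(dir, f)
  ann <- utils::read.delim(fp("annotation.tsv"),
                           colClasses = c(gene = "character",
                                          region = "character",
                                          chrom = "character"),
                           check.names = FALSE)
  ann$gene[is.na(ann$gene)] <- ""
  ann$region[is.na(ann$region)] <- ""
  truth <- jsonlite::read_json(fp("truth.json"), simplifyVector = TRUE)
  truth$true_tissue <- unlist(truth$true_tissue)
  list(
    M = .read_matrix_tsv(fp("intensity_m.tsv")),
    U = .read_matrix_tsv(fp("intensity_u.tsv")),
    detection_p = .read_matrix_tsv(fp("detection_p.tsv")),
    expression = .read_matrix_tsv(fp("expression.tsv")),
    annotation = ann,
    sample_sheet = utils::read.csv(fp("samples.csv"),
                                   colClasses = "character"),
    tf_library = read_gmt(fp("tf_targets.gmt")),
    geneset_library = read_gmt(fp("gene_sets.gmt")),
    truth = truth
  )
}
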