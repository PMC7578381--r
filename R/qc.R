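#' Compute beta values from methylated/unmethylated intensities
#'
#' The methylation level of each probe in each sample is summarised as
#' \eqn{\beta = M / (M + U + 100)}, where \code{M} and \code{U} are the
#' methylated and unmethylated signal intensities. The constant offset in the
#' denominator stabilises low-intensity probes and keeps \eqn{\beta}
#' strictly below 1.
#'
#' @param M numeric matrix of methylated intensities (probes x samples),
#'   with probe ids as rownames and sample ids as colnames.
#' @param U numeric matrix of unmethylated intensities, same shape and
#'   dimnames as \code{M}.
#' @param offset denominator offset (default 100).
#' @return numeric matrix of beta values in \code{[0, 1)}, same dimnames.
#' @export
compute_beta <- function(M, U, offset = 100) {
  if (!is.matrix(M) || !is.matrix(U)) stop("M and U must be matrices")
  if (!identical(dim(M), dim(U))) stop("M and U must have identical dimensions")
  if (!identical(dimnames(M), dimnames(U))) {
    stop("M and U must carry identical probe/sample ids")
  }
  bad <- which(M < 0 | U < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "negative intensity at probe '%s', sample '%s'",
      rownames(M)[bad[1, 1]] %||% bad[1, 1],
      colnames(M)[bad[1, 2]] %||% bad[1, 2]
    ))
  }
  M / (M + U + offset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drop samples with widespread detection failures
#'
#' A sample is dropped when the fraction of its probes with detection
#' p-value at or above \code{p_threshold} reaches \code{frac_threshold}.
#' Both comparisons are inclusive: a probe fails at exactly p = 0.01 and a
#' sample fails at exactly 25\% failing probes, under the defaults.
#'
#' @param detection_p numeric matrix of detection p-values (probes x
#'   samples).
#' @param frac_threshold minimum failing-probe fraction that drops a sample
#'   (default 0.25).
#' @param p_threshold detection p-value at or above which a probe
#'   measurement counts as failed (default 0.01).
#' @return list with \code{kept} (sample ids) and \code{dropped}
#'   (data.frame: sample_id, failing_fraction).
#' @export
drop_failed_samples <- function(detection_p, frac_threshold = 0.25,
                                p_threshold = 0.01) {
  if (!is.matrix(detection_p) || nrow(detection_p) == 0 ||
      ncol(detection_p) == 0) {
    stop("detection_p must be a non-empty matrix")
  }
  frac <- colMeans(detection_p >= p_threshold)
  fail <- frac >= frac_threshold
  list(
    kept = colnames(detection_p)[!fail],
    dropped = data.frame(
      sample_id = colnames(detection_p)[fail],
      failing_fraction = unname(frac[fail]),
      stringsAsFactors = FALSE
    )
  )
}

# QC rule labels, in evaluation order; attribution is first-match.
.qc_probe_rules <- c("detp_50pct", "na_masked", "snp_10bp", "non_cpg",
                     "sex_chrom")

#' Filter probes by detection, masking, SNP, probe-class and chromosome rules
#'
#' A probe is removed when it violates any of, in order: (1) detection
#' p-value >= \code{p_threshold} in at least \code{frac_threshold} of the
#' supplied samples; (2) NA-masked in the manifest; (3) a polymorphic SNP
#' (MAF strictly above \code{maf_threshold}) within 10 bp of the
#' interrogated site; (4) a non-CpG probe class; (5) location on a sex
#' chromosome. The first matching rule is recorded for each removal.
#' Detection fractions should be computed after failed samples have been
#' dropped, so pass the column-subsetted \code{detection_p}.
#'
#' @param annotation probe annotation data.frame (one row per
#'   probe-gene-region mapping; probe-level columns \code{probe_id},
#'   \code{chrom}, \code{probe_class}, \code{snp_within_10bp},
#'   \code{snp_maf}, \code{masked} must be consistent across a probe's rows).
#' @param detection_p detection p-value matrix restricted to retained
#'   samples.
#' @param frac_threshold sample fraction at/above which a failing probe is
#'   removed (default 0.5).
#' @param p_threshold detection p-value failure cutoff (default 0.01).
#' @param maf_threshold minor-allele-frequency cutoff; removal requires MAF
#'   strictly greater (default 0.01).
#' @return list with \code{kept} (probe ids) and \code{dropped}
#'   (data.frame: probe_id, rule).
#' @export
filter_probes <- function(annotation, detection_p, frac_threshold = 0.5,
                          p_threshold = 0.01, maf_threshold = 0.01) {
  probes <- rownames(detection_p)
  ann <- annotation[!duplicated(annotation$probe_id), , drop = FALSE]
  missing <- setdiff(probes, ann$probe_id)
  if (length(missing) > 0) {
    stop("probes missing from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  }
  ann <- ann[match(probes, ann$probe_id), , drop = FALSE]

  detp_fail <- rowMeans(detection_p >= p_threshold) >= frac_threshold
  rule_hits <- cbind(
    detp_50pct = detp_fail,
    na_masked  = ann$masked == 1,
    snp_10bp   = ann$snp_within_10bp == 1 & ann$snp_maf > maf_threshold,
    non_cpg    = ann$probe_class != "cg",
    sex_chrom  = ann$chrom %in% c("X", "Y")
  )
  any_hit <- rowSums(rule_hits) > 0
  first_rule <- .qc_probe_rules[apply(rule_hits, 1, function(h) {
    w <- which(h)
    if (length(w) == 0) NA_integer_ else w[1]
  })]
  list(
    kept = probes[!any_hit],
    dropped = data.frame(
      probe_id = probes[any_hit],
      rule = first_rule[any_hit],
      stringsAsFactors = FALSE
    )
  )
}

#' Flag sample pairs whose tissue labels disagree with methylation clustering
#'
#' Selects the most variable probes, computes 1 - Pearson correlation
#' distances between samples, clusters by average linkage cut at two
#' groups, and flags each sample whose recorded tissue label differs from
#' the majority label of its cluster. A patient is flagged when either
#' member of its tumor/normal pair is flagged. Removal is left to the
#' caller.
#'
#' @param beta beta-value matrix (probes x samples).
#' @param sample_sheet data.frame with columns \code{sample_id},
#'   \code{patient_id}, \code{tissue}.
#' @param n_top number of highest-variance probes used (default 1000);
#'   capped at the probe count with a warning.
#' @return list with \code{flagged_patients}, \code{flagged_samples}, and
#'   the per-sample \code{cluster} assignment.
#' @export
detect_misclassified_pairs <- function(beta, sample_sheet, n_top = 1000) {
  sheet <- sample_sheet[sample_sheet$sample_id %in% colnames(beta), ,
                        drop = FALSE]
  if (nrow(sheet) < 4 || length(unique(sheet$tissue)) < 2) {
    stop("need at least 4 samples covering both tissue labels")
  }
  beta <- beta[, sheet$sample_id, drop = FALSE]
  if (n_top > nrow(beta)) {
    warning(sprintf("n_top = %d exceeds probe count %d; using all probes",
                    n_top, nrow(beta)))
    n_top <- nrow(beta)
  }
  v <- apply(beta, 1, stats::var)
  if (all(v == 0)) {
    warning("all probes have zero variance; clustering is degenerate, no flags")
    return(list(flagged_patients = character(0),
                flagged_samples = character(0),
                cluster = stats::setNames(rep(1L, ncol(beta)), colnames(beta))))
  }
  top <- order(v, decreasing = TRUE)[seq_len(n_top)]
  d <- stats::as.dist(1 - stats::cor(beta[top, , drop = FALSE]))
  cl <- stats::cutree(stats::hclust(d, method = "average"), k = 2)

  flagged_samples <- character(0)
  for (k in unique(cl)) {
    members <- names(cl)[cl == k]
    labs <- sheet$tissue[match(members, sheet$sample_id)]
    tab <- table(labs)
    if (length(tab) > 1 && tab[1] == tab[2]) next  # no majority, no flags
    majority <- names(tab)[which.max(tab)]
    flagged_samples <- c(flagged_samples, members[labs != majority])
  }
  flagged_patients <- sort(unique(
    sheet$patient_id[match(flagged_samples, sheet$sample_id)]
  ))
  list(flagged_patients = flagged_patients,
       flagged_samples = sort(flagged_samples),
       cluster = cl)
}
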