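#' Complete tumor/normal pairs from a sample sheet
#'
#' @param sample_sheet data.frame with columns \code{sample_id},
#'   \code{patient_id}, \code{tissue}; optionally \code{cohort}.
#' @param sample_ids restrict to these samples (e.g. post-QC columns).
#' @return data.frame with one row per complete pair: \code{patient_id},
#'   \code{tumor}, \code{normal} sample ids.
#' @export
paired_samples <- function(sample_sheet, sample_ids = NULL) {
  sheet <- sample_sheet
  if ("cohort" %in% names(sheet)) {
    sheet <- sheet[sheet$cohort == "discovery", , drop = FALSE]
  }
  if (!is.null(sample_ids)) {
    sheet <- sheet[sheet$sample_id %in% sample_ids, , drop = FALSE]
  }
  tum <- sheet[sheet$tissue == "tumor", c("patient_id", "sample_id")]
  nor <- sheet[sheet$tissue == "normal", c("patient_id", "sample_id")]
  pairs <- merge(tum, nor, by = "patient_id", suffixes = c("_t", "_n"))
  data.frame(patient_id = pairs$patient_id,
             tumor = pairs$sample_id_t,
             normal = pairs$sample_id_n,
             stringsAsFactors = FALSE)[order(pairs$patient_id), ]
}

# Paired two-sided test per matrix row. Wilcoxon signed-rank (exact when the
# number of non-zero differences is <= 25, normal approximation with
# continuity correction otherwise) or t-test on logit-transformed values.
# Rows whose paired differences are all zero get p = 1 by convention.
.paired_row_test <- function(x_t, x_n, method = c("wilcoxon", "t_logit")) {
  method <- match.arg(method)
  if (method == "t_logit") {
    clamp <- function(b) pmin(pmax(b, 1e-6), 1 - 1e-6)
    x_t <- log2(clamp(x_t) / (1 - clamp(x_t)))
    x_n <- log2(clamp(x_n) / (1 - clamp(x_n)))
  }
  n <- nrow(x_t)
  p <- numeric(n)
  for (i in seq_len(n)) {
    d <- x_t[i, ] - x_n[i, ]
    if (all(d == 0)) {
      p[i] <- 1
    } else if (method == "wilcoxon") {
      nz <- sum(d != 0)
      p[i] <- suppressWarnings(stats::wilcox.test(
        x_t[i, ], x_n[i, ], paired = TRUE,
        exact = nz <= 25, correct = TRUE
      )$p.value)
    } else {
      p[i] <- stats::t.test(x_t[i, ], x_n[i, ], paired = TRUE)$p.value
    }
  }
  p
}

#' Call differentially methylated positions (DMPs)
#'
#' Per probe, a paired two-sided Wilcoxon signed-rank test on beta values
#' across complete tumor/normal pairs, Benjamini-Hochberg correction across
#' all tested probes, and a mean-difference criterion: a probe is
#' hypermethylated when q < \code{q_threshold} and the mean tumor-minus-
#' normal beta difference is at least \code{delta_threshold},
#' hypomethylated for the mirror image, otherwise not significant.
#'
#' @param beta normalized beta matrix (probes x samples).
#' @param sample_sheet sample sheet; only complete discovery pairs whose
#'   samples appear in \code{beta} are used.
#' @param q_threshold BH-corrected significance cutoff (default 0.05).
#' @param delta_threshold minimum |mean beta difference| (default 0.2).
#' @param method \code{"wilcoxon"} (default) or \code{"t_logit"}, a paired
#'   t-test on logit-scale (M-value-like) beta.
#' @return data.frame: probe_id, delta_beta, p_value, q_value, direction
#'   (\code{hyper}/\code{hypo}/\code{ns}).
#' @export
call_dmps <- function(beta, sample_sheet, q_threshold = 0.05,
                      delta_threshold = 0.2,
                      method = c("wilcoxon", "t_logit")) {
  method <- match.arg(method)
  pairs <- paired_samples(sample_sheet, colnames(beta))
  if (nrow(pairs) == 0) stop("no complete tumor/normal pairs in beta matrix")
  x_t <- beta[, pairs$tumor, drop = FALSE]
  x_n <- beta[, pairs$normal, drop = FALSE]
  delta <- rowMeans(x_t) - rowMeans(x_n)
  p <- .paired_row_test(x_t, x_n, method)
  q <- stats::p.adjust(p, method = "BH")
  direction <- ifelse(
    q < q_threshold & delta >= delta_threshold, "hyper",
    ifelse(q < q_threshold & delta <= -delta_threshold, "hypo", "ns")
  )
  data.frame(probe_id = rownames(beta), delta_beta = unname(delta),
             p_value = unname(p), q_value = unname(q),
             direction = unname(direction), stringsAsFactors = FALSE)
}

# Manifest sub-region -> gene-region group used for DMR calling.
.region_group_map <- c(TSS1500 = "promoter", TSS200 = "promoter",
                       `5UTR` = "promoter", `1stExon` = "body",
                       Body = "body", `3UTR` = "3UTR")

#' Build a gene-region index from probe annotation
#'
#' Collapses manifest sub-regions (TSS1500, TSS200, 5'UTR into the
#' promoter; 1stExon and Body into the gene body; 3'UTR standing alone)
#' while retaining per-subregion membership. Probes mapping to several
#' genes or regions keep every mapping.
#'
#' @param annotation probe annotation (one row per probe-gene-region
#'   mapping; empty \code{gene} rows are intergenic and skipped).
#' @param probe_ids optionally restrict to these probes (post-QC).
#' @return list with \code{groups} (data.frame: gene, region_group,
#'   probe_id, unique rows) and \code{subregions} (data.frame: gene,
#'   region, probe_id).
#' @export
build_region_index <- function(annotation, probe_ids = NULL) {
  ann <- annotation[!is.na(annotation$gene) & annotation$gene != "", ,
                    drop = FALSE]
  if (!is.null(probe_ids)) ann <- ann[ann$probe_id %in% probe_ids, ,
                                      drop = FALSE]
  bad <- setdiff(unique(ann$region), names(.region_group_map))
  if (length(bad) > 0) stop("unknown region values: ",
                            paste(bad, collapse = ", "))
  groups <- unique(data.frame(
    gene = ann$gene,
    region_group = unname(.region_group_map[ann$region]),
    probe_id = ann$probe_id, stringsAsFactors = FALSE))
  subregions <- unique(ann[, c("gene", "region", "probe_id")])
  rownames(groups) <- rownames(subregions) <- NULL
  list(groups = groups, subregions = subregions)
}

#' Direction verdict for a gene region under the unidirectional-DMP rule
#'
#' A region is called in a direction when at least \code{min_fraction} of
#' its mapped probes are DMPs in that direction and strictly fewer than
#' \code{min_fraction} are DMPs in the opposite direction; regions meeting
#' the fraction in both directions are \code{ambiguous}; all others are
#' \code{none}. Vectorised.
#'
#' @param n_probes,n_hyper,n_hypo integer vectors (probes mapped to the
#'   region; hyper- and hypomethylated DMPs among them).
#' @param min_fraction unidirectional-DMP fraction cutoff (default 0.25).
#' @return character vector in \code{hyper}, \code{hypo}, \code{ambiguous},
#'   \code{none}.
#' @export
dmr_direction <- function(n_probes, n_hyper, n_hypo, min_fraction = 0.25) {
  fh <- n_hyper / n_probes
  fl <- n_hypo / n_probes
  ifelse(fh >= min_fraction & fl >= min_fraction, "ambiguous",
         ifelse(fh >= min_fraction, "hyper",
                ifelse(fl >= min_fraction, "hypo", "none")))
}

#' Call differentially methylated regions (DMRs)
#'
#' Per (gene, region group): counts hyper- and hypomethylated DMPs among
#' the region's mapped probes and assigns a direction by the
#' unidirectional-fraction rule (\code{\link{dmr_direction}}); the fraction
#' denominator is all mapped probes surviving filtering, so it is defined
#' even for regions without DMPs. When \code{beta} and \code{sample_sheet}
#' are supplied, the region's methylation level is quantified as the mean
#' beta of its DMPs per tissue.
#'
#' @param dmps DMP table from \code{\link{call_dmps}}.
#' @param index region index from \code{\link{build_region_index}}.
#' @param beta optional beta matrix for per-tissue region means.
#' @param sample_sheet required with \code{beta}.
#' @param min_fraction unidirectional fraction cutoff (default 0.25).
#' @return list with \code{dmrs} (directional regions only) and \code{full}
#'   (every region, including \code{ambiguous} and \code{none}); columns:
#'   gene, region_group, n_probes, n_hyper_dmps, n_hypo_dmps,
#'   unidirectional_fraction, direction, avg_beta_tumor, avg_beta_normal.
#' @export
call_dmrs <- function(dmps, index, beta = NULL, sample_sheet = NULL,
                      min_fraction = 0.25) {
  idx <- index$groups
  known <- idx$probe_id %in% dmps$probe_id
  if (!all(known)) {
    warning(sprintf("%d region-probe mappings absent from DMP table; dropped",
                    sum(!known)))
    idx <- idx[known, , drop = FALSE]
  }
  if (nrow(idx) == 0) stop("region index is empty after alignment")
  idx$direction <- dmps$direction[match(idx$probe_id, dmps$probe_id)]
  key <- paste(idx$gene, idx$region_group, sep = "\r")
  n_probes <- tapply(idx$probe_id, key, length)
  n_hyper <- tapply(idx$direction == "hyper", key, sum)
  n_hypo <- tapply(idx$direction == "hypo", key, sum)
  keys <- names(n_probes)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    gene = vapply(parts, `[`, "", 1),
    region_group = vapply(parts, `[`, "", 2),
    n_probes = as.integer(n_probes),
    n_hyper_dmps = as.integer(n_hyper),
    n_hypo_dmps = as.integer(n_hypo),
    stringsAsFactors = FALSE
  )
  out$unidirectional_fraction <-
    pmax(out$n_hyper_dmps, out$n_hypo_dmps) / out$n_probes
  out$direction <- dmr_direction(out$n_probes, out$n_hyper_dmps,
                                 out$n_hypo_dmps, min_fraction)
  out$avg_beta_tumor <- NA_real_
  out$avg_beta_normal <- NA_real_
  if (!is.null(beta)) {
    if (is.null(sample_sheet)) stop("sample_sheet required with beta")
    pairs <- paired_samples(sample_sheet, colnames(beta))
    dmp_probes <- dmps$probe_id[dmps$direction != "ns"]
    for (i in seq_len(nrow(out))) {
      pr <- idx$probe_id[key == keys[i]]
      pr <- intersect(pr, dmp_probes)
      if (length(pr) == 0) next
      out$avg_beta_tumor[i] <- mean(beta[pr, pairs$tumor, drop = FALSE])
      out$avg_beta_normal[i] <- mean(beta[pr, pairs$normal, drop = FALSE])
    }
  }
  out <- out[order(out$gene, out$region_group), ]
  rownames(out) <- NULL
  list(dmrs = out[out$direction %in% c("hyper", "hypo"), , drop = FALSE],
       full = out)
}

#' Cross-tabulate DMP direction by CpG-island context
#'
#' Shores and shelves are collapsed over their N/S orientation, yielding
#' classes Island, Shore, Shelf and OpenSea; counts and within-class
#' percentages are reported for hyper- and hypomethylated DMPs.
#'
#' @param dmps DMP table.
#' @param annotation probe annotation carrying \code{cgi_relation}.
#' @return data.frame: cgi_class, n_hyper, n_hypo, n_dmps, pct_hyper,
#'   pct_hypo. Empty (zero rows) when there are no DMPs.
#' @export
summarize_cgi_distribution <- function(dmps, annotation) {
  ann <- annotation[!duplicated(annotation$probe_id), , drop = FALSE]
  valid <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")
  bad <- setdiff(unique(ann$cgi_relation), valid)
  if (length(bad) > 0) stop("unknown cgi_relation values: ",
                            paste(bad, collapse = ", "))
  collapse <- c(Island = "Island", N_Shore = "Shore", S_Shore = "Shore",
                N_Shelf = "Shelf", S_Shelf = "Shelf", OpenSea = "OpenSea")
  sig <- dmps[dmps$direction %in% c("hyper", "hypo"), , drop = FALSE]
  empty <- data.frame(cgi_class = character(0), n_hyper = integer(0),
                      n_hypo = integer(0), n_dmps = integer(0),
                      pct_hyper = numeric(0), pct_hypo = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(sig) == 0) return(empty)
  cls <- collapse[ann$cgi_relation[match(sig$probe_id, ann$probe_id)]]
  tab <- table(factor(cls, levels = unique(collapse)), sig$direction)
  n_hyper <- if ("hyper" %in% colnames(tab)) tab[, "hyper"] else 0L
  n_hypo <- if ("hypo" %in% colnames(tab)) tab[, "hypo"] else 0L
  out <- data.frame(cgi_class = rownames(tab),
                    n_hyper = as.integer(n_hyper),
                    n_hypo = as.integer(n_hypo),
                    stringsAsFactors = FALSE)
  out$n_dmps <- out$n_hyper + out$n_hypo
  out$pct_hyper <- ifelse(out$n_dmps > 0, 100 * out$n_hyper / out$n_dmps, NA)
  out$pct_hypo <- ifelse(out$n_dmps > 0, 100 * out$n_hypo / out$n_dmps, NA)
  rownames(out) <- NULL
  out
}

#' Region-level verification by paired Wilcoxon on region-mean beta
#'
#' An independent route to region calls: per (gene, region group) each
#' sample is summarised by its mean beta over all of the region's probes;
#' the region means are compared across complete pairs by a paired
#' Wilcoxon signed-rank test with BH correction across regions. A region
#' is verified when q < \code{q_threshold}, directed by the sign of the
#' mean paired difference.
#'
#' @param beta normalized beta matrix.
#' @param index region index from \code{\link{build_region_index}}.
#' @param sample_sheet sample sheet (complete discovery pairs used).
#' @param q_threshold BH cutoff (default 0.05).
#' @return data.frame: gene, region_group, n_probes, delta_beta, p_value,
#'   q_value, verified, direction.
#' @export
verify_dmrs_regionwise <- function(beta, index, sample_sheet,
                                   q_threshold = 0.05) {
  pairs <- paired_samples(sample_sheet, colnames(beta))
  if (nrow(pairs) == 0) stop("no complete tumor/normal pairs in beta matrix")
  idx <- index$groups[index$groups$probe_id %in% rownames(beta), ,
                      drop = FALSE]
  if (nrow(idx) == 0) stop("no region probes present in beta matrix")
  key <- paste(idx$gene, idx$region_group, sep = "\r")
  ukeys <- unique(key)
  m_t <- matrix(0, length(ukeys), nrow(pairs))
  m_n <- matrix(0, length(ukeys), nrow(pairs))
  for (i in seq_along(ukeys)) {
    pr <- idx$probe_id[key == ukeys[i]]
    m_t[i, ] <- colMeans(beta[pr, pairs$tumor, drop = FALSE])
    m_n[i, ] <- colMeans(beta[pr, pairs$normal, drop = FALSE])
  }
  p <- .paired_row_test(m_t, m_n, "wilcoxon")
  q <- stats::p.adjust(p, method = "BH")
  delta <- rowMeans(m_t) - rowMeans(m_n)
  parts <- strsplit(ukeys, "\r", fixed = TRUE)
  out <- data.frame(
    gene = vapply(parts, `[`, "", 1),
    region_group = vapply(parts, `[`, "", 2),
    n_probes = as.integer(table(key)[ukeys]),
    delta_beta = delta, p_value = p, q_value = q,
    verified = q < q_threshold,
    direction = ifelse(q < q_threshold,
                       ifelse(delta > 0, "hyper", "hypo"), "ns"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene, out$region_group), ]
  rownames(out) <- NULL
  out
}

#' Overlap between primary DMRs and region-level verification
#'
#' @param dmrs directional DMR table (the \code{dmrs} element of
#'   \code{\link{call_dmrs}}).
#' @param verification table from \code{\link{verify_dmrs_regionwise}}.
#' @return list with per-direction and overall fractions of primary DMRs
#'   whose region is verified in the same direction.
#' @export
verification_overlap <- function(dmrs, verification) {
  vkey <- paste(verification$gene, verification$region_group,
                verification$direction)
  frac <- function(d) {
    sub <- dmrs[dmrs$direction == d, , drop = FALSE]
    if (nrow(sub) == 0) return(NA_real_)
    mean(paste(sub$gene, sub$region_group, d) %in% vkey)
  }
  overall <- {
    sub <- dmrs[dmrs$direction %in% c("hyper", "hypo"), , drop = FALSE]
    if (nrow(sub) == 0) NA_real_
    else mean(paste(sub$gene, sub$region_group, sub$direction) %in% vkey)
  }
  list(hyper = frac("hyper"), hypo = frac("hypo"), overall = overall)
}

#' Per-patient promoter methylation change matrix
#'
#' For each gene with promoter DMPs, the per-patient change is the mean,
#' over the gene's promoter DMP probes, of tumor beta minus the paired
#' normal beta.
#'
#' @param beta normalized beta matrix.
#' @param index region index.
#' @param dmps DMP table.
#' @param sample_sheet sample sheet.
#' @param genes restrict to these genes (default: all genes with promoter
#'   DMPs).
#' @return genes x patients matrix of mean promoter beta differences.
#' @export
promoter_delta_beta <- function(beta, index, dmps, sample_sheet,
                                genes = NULL) {
  pairs <- paired_samples(sample_sheet, colnames(beta))
  prom <- index$groups[index$groups$region_group == "promoter", ,
                      drop = FALSE]
  dmp_probes <- dmps$probe_id[dmps$direction != "ns"]
  prom <- prom[prom$probe_id %in% intersect(dmp_probes, rownames(beta)), ,
               drop = FALSE]
  if (!is.null(genes)) prom <- prom[prom$gene %in% genes, , drop = FALSE]
  glist <- split(prom$probe_id, prom$gene)
  if (length(glist) == 0) stop("no genes with promoter DMPs")
  out <- matrix(NA_real_, length(glist), nrow(pairs),
                dimnames = list(names(glist), pairs$patient_id))
  for (g in seq_along(glist)) {
    pr <- glist[[g]]
    d <- beta[pr, pairs$tumor, drop = FALSE] -
      beta[pr, pairs$normal, drop = FALSE]
    out[g, ] <- colMeans(d)
  }
  out
}

#' Cluster patients on per-patient promoter methylation change
#'
#' Average-linkage hierarchical clustering with Euclidean distance over the
#' patient columns, cut at \code{k}; the larger cluster is recursively cut
#' at \code{sub_k}. Final clusters are ordered by decreasing mean absolute
#' methylation change (severe, moderate, mild, ...).
#'
#' @param delta_beta genes x patients matrix (e.g. from
#'   \code{\link{promoter_delta_beta}}).
#' @param k number of top-level clusters (default 2).
#' @param sub_k number of sub-clusters for the larger cluster (default 2).
#' @return list with \code{labels} (named integer vector, severity-ordered:
#'   1 = most severe) and \code{summary} (cluster sizes and mean |change|).
#' @export
cluster_patients <- function(delta_beta, k = 2, sub_k = 2) {
  n <- ncol(delta_beta)
  if (k > n) stop(sprintf("k = %d exceeds patient count %d", k, n))
  d <- stats::dist(t(delta_beta))
  if (all(d == 0)) {
    warning("all patients identical; single effective cluster")
    labels <- stats::setNames(rep(1L, n), colnames(delta_beta))
    return(list(labels = labels,
                summary = data.frame(cluster = 1L, n = n,
                                     mean_abs_delta = mean(abs(delta_beta)))))
  }
  top <- stats::cutree(stats::hclust(d, method = "average"), k = k)
  labels <- top
  sizes <- table(top)
  big <- as.integer(names(sizes)[which.max(sizes)])
  members <- names(top)[top == big]
  if (sub_k > 1 && length(members) > sub_k) {
    sub <- delta_beta[, members, drop = FALSE]
    ds <- stats::dist(t(sub))
    if (!all(ds == 0)) {
      subcl <- stats::cutree(stats::hclust(ds, method = "average"),
                             k = sub_k)
      labels[members] <- max(top) + subcl
      labels <- stats::setNames(match(labels, sort(unique(labels))),
                                names(labels))
    }
  }
  mean_abs <- vapply(sort(unique(labels)), function(cl) {
    mean(abs(delta_beta[, names(labels)[labels == cl], drop = FALSE]))
  }, 0)
  sev_order <- order(mean_abs, decreasing = TRUE)
  relabel <- match(labels, sort(unique(labels))[sev_order])
  labels <- stats::setNames(as.integer(relabel), names(labels))
  summary <- data.frame(
    cluster = seq_along(sev_order),
    n = as.integer(table(labels)[as.character(seq_along(sev_order))]),
    mean_abs_delta = mean_abs[sev_order]
  )
  list(labels = labels, summary = summary)
}

#' Export DMPs as BED intervals
#'
#' Writes significant DMPs as 0-based half-open single-base intervals with
#' the probe id as name and 1000 x |mean beta difference| (capped at 1000)
#' as score, for genome-browser use.
#'
#' @param dmps DMP table.
#' @param annotation probe annotation with \code{chrom} and 1-based
#'   \code{pos}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_dmp_bed <- function(dmps, annotation, path) {
  ann <- annotation[!duplicated(annotation$probe_id), , drop = FALSE]
  sig <- dmps[dmps$direction %in% c("hyper", "hypo"), , drop = FALSE]
  m <- match(sig$probe_id, ann$probe_id)
  bed <- data.frame(
    chrom = paste0("chr", ann$chrom[m]),
    start = ann$pos[m] - 1L,
    end = ann$pos[m],
    name = sig$probe_id,
    score = pmin(round(1000 * abs(sig$delta_beta)), 1000L)
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
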