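#' Classify epigenetically silenced and overexpressed genes
#'
#' A gene is epigenetically silenced when its promoter region is
#' hypermethylated and its expression is down in tumor; epigenetically
#' overexpressed when its promoter is hypomethylated and expression is up.
#' Genes with ambiguous promoter direction are never classified.
#'
#' @param promoter_dmrs DMR table (only \code{region_group == "promoter"}
#'   rows are used; one row per gene).
#' @param degs differential-expression table from \code{\link{call_degs}}.
#' @return data.frame: gene, epi_class (\code{silenced}/
#'   \code{overexpressed}), promoter_direction, de_direction, log2_fc.
#' @export
classify_epigenetic_genes <- function(promoter_dmrs, degs) {
  prom <- promoter_dmrs[promoter_dmrs$region_group == "promoter", ,
                        drop = FALSE]
  if (anyDuplicated(prom$gene)) {
    stop("duplicate gene rows in promoter DMR table: ",
         paste(unique(prom$gene[duplicated(prom$gene)]), collapse = ", "))
  }
  if (anyDuplicated(degs$gene)) {
    stop("duplicate gene rows in DE table: ",
         paste(unique(degs$gene[duplicated(degs$gene)]), collapse = ", "))
  }
  merged <- merge(prom[, c("gene", "direction")],
                  degs[, c("gene", "direction", "log2_fc")],
                  by = "gene", suffixes = c("_prom", "_de"))
  cls <- ifelse(merged$direction_prom == "hyper" &
                  merged$direction_de == "down", "silenced",
                ifelse(merged$direction_prom == "hypo" &
                         merged$direction_de == "up", "overexpressed", NA))
  out <- data.frame(gene = merged$gene, epi_class = cls,
                    promoter_direction = merged$direction_prom,
                    de_direction = merged$direction_de,
                    log2_fc = merged$log2_fc, stringsAsFactors = FALSE)
  out <- out[!is.na(out$epi_class), , drop = FALSE]
  out <- out[order(out$gene), ]
  rownames(out) <- NULL
  out
}

# All permutations of 1..n as a matrix (n! rows); used for the exact
# Spearman null at small n.
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, 1] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rank correlation with average ranks for ties; the two-sided p-value is
#' computed by exact enumeration of all rank permutations when n <= 9 and
#' by the t-distribution approximation otherwise.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return list with \code{rho} and \code{p} (both NA when either input
#'   has zero variance).
#' @export
spearman_rho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- .permutations(n)
    rho_null <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = min(p, 1))
}

#' Correlate promoter methylation with expression across samples
#'
#' For each gene, x is the per-sample mean beta over the gene's promoter
#' DMP probes (all promoter probes when no DMP list is supplied) and y is
#' per-sample \code{log2(FPKM + 1)}; the correlation is computed over all
#' paired samples (tumor and normal) shared by both assays. The
#' significance flag follows the double threshold rho <
#' \code{rho_threshold} and p < \code{p_threshold} on the raw p-value (no
#' multiplicity correction).
#'
#' @param beta normalized beta matrix.
#' @param index region index from \code{\link{build_region_index}}.
#' @param expr FPKM matrix.
#' @param sample_sheet sample sheet.
#' @param genes genes to evaluate.
#' @param dmps optional DMP table restricting promoter probes to DMPs.
#' @param rho_threshold correlation cutoff (default -0.5, strict less-than).
#' @param p_threshold raw p cutoff (default 0.05, strict).
#' @param tumor_only use tumor samples only (default FALSE: tumor+normal).
#' @return data.frame: gene, n_samples, rho, p, significantly_correlated.
#' @export
correlate_promoter_expression <- function(beta, index, expr, sample_sheet,
                                          genes, dmps = NULL,
                                          rho_threshold = -0.5,
                                          p_threshold = 0.05,
                                          tumor_only = FALSE) {
  pairs <- paired_samples(sample_sheet,
                          intersect(colnames(beta), colnames(expr)))
  samples <- if (tumor_only) pairs$tumor else c(pairs$tumor, pairs$normal)
  if (length(samples) < 4) stop("need expression and methylation in >= 4 shared samples")
  prom <- index$groups[index$groups$region_group == "promoter" &
                         index$groups$gene %in% genes, , drop = FALSE]
  prom <- prom[prom$probe_id %in% rownames(beta), , drop = FALSE]
  if (!is.null(dmps)) {
    dmp_probes <- dmps$probe_id[dmps$direction != "ns"]
    restricted <- prom[prom$probe_id %in% dmp_probes, , drop = FALSE]
    # fall back to all promoter probes for genes left without any probe
    keep_all <- setdiff(prom$gene, restricted$gene)
    prom <- rbind(restricted, prom[prom$gene %in% keep_all, , drop = FALSE])
  }
  out <- data.frame(gene = genes, n_samples = NA_integer_, rho = NA_real_,
                    p = NA_real_, significantly_correlated = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    g <- genes[i]
    pr <- prom$probe_id[prom$gene == g]
    if (length(pr) == 0 || !(g %in% rownames(expr))) next
    x <- colMeans(beta[pr, samples, drop = FALSE])
    y <- log2(expr[g, samples] + 1)
    out$n_samples[i] <- length(samples)
    sp <- spearman_rho(x, y)
    out$rho[i] <- sp$rho
    out$p[i] <- sp$p
    out$significantly_correlated[i] <-
      !is.na(sp$rho) && sp$rho < rho_threshold && sp$p < p_threshold
  }
  out
}
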