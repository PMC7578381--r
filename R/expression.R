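#' Count expressed genes per sample
#'
#' A gene counts as expressed in a sample when its FPKM is strictly above
#' \code{fpkm_threshold}.
#'
#' @param expr FPKM matrix (genes x samples), non-negative.
#' @param sample_sheet sample sheet for per-tissue averaging.
#' @param fpkm_threshold expression floor (default 0.1, strict).
#' @return list with \code{per_sample} (named counts) and
#'   \code{tissue_means}.
#' @export
count_expressed_genes <- function(expr, sample_sheet, fpkm_threshold = 0.1) {
  if (any(expr < 0)) stop("FPKM values must be non-negative")
  counts <- colSums(expr > fpkm_threshold)
  tissue <- sample_sheet$tissue[match(colnames(expr),
                                      sample_sheet$sample_id)]
  list(per_sample = counts,
       tissue_means = tapply(counts, tissue, mean))
}

#' Call differentially expressed genes on a gene-level FPKM matrix
#'
#' Per gene, a paired two-sided Wilcoxon signed-rank test on
#' \code{log2(FPKM + 1)} across complete tumor/normal pairs, BH correction,
#' and a shrunken fold change \code{log2((mean_tumor + eps) /
#' (mean_normal + eps))}. Significance requires q < \code{q_threshold};
#' there is no fold-change floor by default. A precomputed differential-
#' expression table (columns gene, log2_fc, p, q) may be supplied instead,
#' e.g. from an external aligner/assembler pipeline, and is classified
#' under the same thresholds.
#'
#' @param expr FPKM matrix (genes x samples).
#' @param sample_sheet sample sheet.
#' @param q_threshold BH cutoff (default 0.05).
#' @param eps fold-change pseudocount on mean FPKM (default 1).
#' @param external optional precomputed table (gene, log2_fc, p, q).
#' @return data.frame: gene, mean_fpkm_tumor, mean_fpkm_normal, log2_fc,
#'   p_value, q_value, direction (\code{up}/\code{down}/\code{ns}).
#' @export
call_degs <- function(expr, sample_sheet, q_threshold = 0.05, eps = 1,
                      external = NULL) {
  if (!is.null(external)) {
    need <- c("gene", "log2_fc", "p", "q")
    if (!all(need %in% names(external))) {
      stop("external DE table needs columns: ", paste(need, collapse = ", "))
    }
    direction <- ifelse(external$q < q_threshold & external$log2_fc > 0, "up",
                        ifelse(external$q < q_threshold & external$log2_fc < 0,
                               "down", "ns"))
    return(data.frame(gene = external$gene,
                      mean_fpkm_tumor = NA_real_,
                      mean_fpkm_normal = NA_real_,
                      log2_fc = external$log2_fc,
                      p_value = external$p, q_value = external$q,
                      direction = direction, stringsAsFactors = FALSE))
  }
  pairs <- paired_samples(sample_sheet, colnames(expr))
  if (nrow(pairs) < 2) stop("need at least 2 complete pairs")
  complete <- rowSums(is.na(expr[, c(pairs$tumor, pairs$normal),
                                 drop = FALSE])) == 0
  if (!all(complete)) {
    message(sprintf("%d genes with missing values excluded", sum(!complete)))
    expr <- expr[complete, , drop = FALSE]
  }
  x_t <- expr[, pairs$tumor, drop = FALSE]
  x_n <- expr[, pairs$normal, drop = FALSE]
  mean_t <- rowMeans(x_t)
  mean_n <- rowMeans(x_n)
  log2_fc <- log2((mean_t + eps) / (mean_n + eps))
  p <- .paired_row_test(log2(x_t + 1), log2(x_n + 1), "wilcoxon")
  q <- stats::p.adjust(p, method = "BH")
  direction <- ifelse(q < q_threshold & log2_fc > 0, "up",
                      ifelse(q < q_threshold & log2_fc < 0, "down", "ns"))
  data.frame(gene = rownames(expr),
             mean_fpkm_tumor = unname(mean_t),
             mean_fpkm_normal = unname(mean_n),
             log2_fc = unname(log2_fc),
             p_value = unname(p), q_value = unname(q),
             direction = unname(direction), stringsAsFactors = FALSE)
}
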