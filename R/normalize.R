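#' Within-array SWAN-style correction of Infinium design-type bias
#'
#' The two Infinium probe chemistries on 450K-style arrays produce
#' systematically different intensity (and hence beta) distributions. This
#' subset-quantile within-array scheme corrects each sample and channel
#' (methylated, unmethylated) separately: probes are stratified by the
#' number of CpGs underlying the probe (1, 2, >= 3); within each stratum an
#' equal-size random subset of type-I and type-II probes is drawn (seeded);
#' the per-type pooled subsets define two empirical quantile functions whose
#' mean becomes the reference; each type's subset intensities are mapped
#' onto the reference by rank, and all remaining probes of that type are
#' adjusted by monotone interpolation between flanking adjusted subset
#' values. The per-type map is monotone, so within-type rank order is
#' preserved.
#'
#' @param M,U intensity matrices (probes x samples), identical dimnames.
#' @param annotation probe annotation with columns \code{probe_id},
#'   \code{design_type} (\code{"I"}/\code{"II"}) and \code{n_cpgs_in_probe}.
#' @param seed integer seed governing subset selection.
#' @return list with adjusted \code{M} and \code{U} matrices (non-negative,
#'   same dimnames) and \code{provenance} (seed, subset size per type).
#' @export
swan_normalize <- function(M, U, annotation, seed = 1L) {
  if (!identical(dimnames(M), dimnames(U))) {
    stop("M and U must carry identical probe/sample ids")
  }
  ann <- annotation[!duplicated(annotation$probe_id), , drop = FALSE]
  ann <- ann[match(rownames(M), ann$probe_id), , drop = FALSE]
  if (anyNA(ann$probe_id)) stop("annotation must cover every probe in M/U")
  if (!all(c("design_type", "n_cpgs_in_probe") %in% names(ann))) {
    stop("annotation must provide design_type and n_cpgs_in_probe")
  }
  stratum <- pmin(ann$n_cpgs_in_probe, 3L)
  is1 <- ann$design_type == "I"
  is2 <- ann$design_type == "II"

  # Seeded, stratified subset: per stratum, min(count I, count II) probes of
  # each type; strata with < 2 probes of either type are skipped.
  sub1 <- integer(0); sub2 <- integer(0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  for (s in sort(unique(stratum))) {
    i1 <- which(is1 & stratum == s)
    i2 <- which(is2 & stratum == s)
    n_s <- min(length(i1), length(i2))
    if (n_s < 2) {
      warning(sprintf(
        "stratum n_cpgs=%s has <2 probes of one design type; skipped", s))
      next
    }
    sub1 <- c(sub1, sample(i1, n_s))
    sub2 <- c(sub2, sample(i2, n_s))
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  if (length(sub1) == 0) {
    warning("no usable strata; intensities returned unadjusted")
    return(list(M = M, U = U,
                provenance = list(seed = seed, subset_size = 0L)))
  }

  adjust_channel <- function(x) {
    out <- x
    for (j in seq_len(ncol(x))) {
      q1 <- sort(x[sub1, j])
      q2 <- sort(x[sub2, j])
      ref <- (q1 + q2) / 2
      for (idx in list(list(sub = sub1, all = which(is1)),
                       list(sub = sub2, all = which(is2)))) {
        qt <- sort(x[idx$sub, j])
        # monotone map from the subset's own quantiles onto the reference;
        # rule = 2 clamps probes outside the subset range to the extremes
        out[idx$all, j] <- stats::approx(qt, ref, xout = x[idx$all, j],
                                         rule = 2, ties = "ordered")$y
      }
    }
    pmax(out, 0)
  }

  list(
    M = adjust_channel(M),
    U = adjust_channel(U),
    provenance = list(seed = seed, subset_size = length(sub1))
  )
}

#' Between-sample quantile normalization of beta values
#'
#' Classic quantile normalization: each sample's values are replaced by the
#' across-sample mean of the order statistics at their rank; tied values
#' receive the mean of their rank positions' reference values. Afterwards
#' every sample shares the same sorted value vector (up to ties).
#'
#' @param beta beta-value matrix (probes x samples), no missing values.
#' @return normalized beta matrix, same dimnames, values in \code{[0, 1]}.
#' @export
quantile_normalize_beta <- function(beta) {
  if (anyNA(beta)) stop("beta must contain no missing values")
  if (ncol(beta) == 1) {
    warning("single sample: quantile normalization is the identity")
    return(beta)
  }
  out <- limma::normalizeQuantiles(beta, ties = TRUE)
  dimnames(out) <- dimnames(beta)
  out
}
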