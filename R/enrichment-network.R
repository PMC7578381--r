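#' Read a GMT gene-set library
#'
#' Tab-separated lines: set id, description, then member gene symbols.
#' Member symbols are uppercased and deduplicated (with a warning when
#' duplicates are found).
#'
#' @param path GMT file path.
#' @return named list of character vectors; the \code{description}
#'   attribute carries per-set descriptions.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    out <- list()
    attr(out, "description") <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop(sprintf("GMT parse error at line %d: fewer than 3 fields", short[1]))
  }
  ids <- vapply(fields, `[`, "", 1)
  desc <- vapply(fields, `[`, "", 2)
  sets <- lapply(fields, function(f) toupper(f[-(1:2)]))
  ndup <- sum(vapply(sets, function(s) sum(duplicated(s)), 0L))
  if (ndup > 0) warning(sprintf("%d duplicate member genes removed", ndup))
  sets <- lapply(sets, unique)
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(desc, ids)
  sets
}

#' Write a GMT gene-set library
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional named descriptions (default \code{"na"}).
#' @return invisibly, the path.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) {
    description <- stats::setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(id) {
    paste(c(id, description[[id]], sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Two-sided hypergeometric gene-set enrichment with step-down correction
#'
#' For each set, with universe size N, set size K (after intersection with
#' the universe), query size n and overlap k, the enrichment tail is
#' P[X >= k] and the depletion tail P[X <= k] under the hypergeometric
#' law; the two-sided p-value is twice the smaller tail, capped at 1.
#' P-values are corrected across all tested sets by the Bonferroni
#' step-down (Holm) procedure; a set is significant when the corrected p
#' falls below \code{alpha}.
#'
#' @param query_genes character vector (must be a subset of the universe).
#' @param library named list of gene sets (e.g. from \code{\link{read_gmt}}).
#' @param universe character vector of all assayable genes.
#' @param alpha corrected-p significance cutoff (default 0.05).
#' @return data.frame sorted by corrected p: term_id, set_size,
#'   overlap_count, overlap_genes (comma-joined), p_two_sided, p_corrected,
#'   significant.
#' @export
hypergeometric_enrich <- function(query_genes, library, universe,
                                  alpha = 0.05) {
  query <- unique(toupper(query_genes))
  universe <- unique(toupper(universe))
  if (length(query) == 0) stop("empty query gene list")
  stray <- setdiff(query, universe)
  if (length(stray) > 0) {
    stop("query genes missing from universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(library), function(id) {
    set <- intersect(toupper(library[[id]]), universe)
    K <- length(set)
    ov <- intersect(query, set)
    k <- length(ov)
    p_enrich <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    p_deplete <- stats::phyper(k, K, N - K, n, lower.tail = TRUE)
    data.frame(term_id = id, set_size = K, overlap_count = k,
               overlap_genes = paste(sort(ov), collapse = ","),
               p_two_sided = min(1, 2 * min(p_enrich, p_deplete)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- stats::p.adjust(out$p_two_sided, method = "holm")
  out$significant <- out$p_corrected < alpha
  out <- out[order(out$p_corrected, out$p_two_sided, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Cohen's kappa between two gene sets over a reference universe
#'
#' Chance-corrected agreement of the two membership indicator vectors over
#' \code{universe}: \eqn{\kappa = (p_o - p_e) / (1 - p_e)}.
#'
#' @param set_a,set_b character vectors.
#' @param universe reference gene universe.
#' @return numeric kappa (NA when the expected agreement is 1).
#' @export
cohen_kappa_sets <- function(set_a, set_b, universe) {
  a <- universe %in% set_a
  b <- universe %in% set_b
  n <- length(universe)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (abs(1 - pe) < .Machine$double.eps) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Group enriched terms by kappa similarity of their overlap genes
#'
#' Pairwise kappa between significant terms is computed from their
#' 2x2 gene-membership tables over the union of all significant terms'
#' overlap genes; terms joined by kappa at or above the threshold (graph
#' connected components) form a group; each group's leader is the term
#' with the lowest corrected p (ties broken by larger overlap, then
#' lexicographic term id).
#'
#' @param results enrichment table from
#'   \code{\link{hypergeometric_enrich}}.
#' @param kappa_threshold grouping threshold (default 0.4, inclusive).
#' @return the significant rows of \code{results} with added
#'   \code{group_id} and \code{is_group_leader} columns.
#' @export
kappa_group_terms <- function(results, kappa_threshold = 0.4) {
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    sig$group_id <- integer(0)
    sig$is_group_leader <- logical(0)
    return(sig)
  }
  sets <- strsplit(sig$overlap_genes, ",", fixed = TRUE)
  sets <- lapply(sets, function(s) s[nzchar(s)])
  uni <- sort(unique(unlist(sets)))
  m <- nrow(sig)
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (m > 1 && length(uni) > 0) {
    edges <- integer(0)
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        kp <- cohen_kappa_sets(sets[[i]], sets[[j]], uni)
        if (!is.na(kp) && kp >= kappa_threshold) edges <- c(edges, i, j)
      }
    }
    if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  }
  comp <- igraph::components(g)$membership
  sig$group_id <- as.integer(comp)
  sig$is_group_leader <- FALSE
  for (grp in unique(sig$group_id)) {
    idx <- which(sig$group_id == grp)
    ord <- idx[order(sig$p_corrected[idx], -sig$overlap_count[idx],
                     sig$term_id[idx])]
    sig$is_group_leader[ord[1]] <- TRUE
  }
  rownames(sig) <- NULL
  sig
}

#' Build a transcription-factor target network over a query gene list
#'
#' Directed edges run from a TF to each of its library targets present in
#' the query list; TFs that themselves appear in the query (e.g. are
#' epigenetically regulated) are flagged.
#'
#' @param tf_library named list: TF id -> target gene symbols.
#' @param query_genes character vector of genes of interest.
#' @param epi_status optional named vector gene -> class
#'   (\code{silenced}/\code{overexpressed}); used to annotate nodes.
#' @return list with \code{edges} (data.frame source, target, interaction),
#'   \code{nodes} (data.frame id, role, epi_class), and \code{out_degree}
#'   (named integer vector over TFs with at least one edge).
#' @export
build_tf_network <- function(tf_library, query_genes, epi_status = NULL) {
  query <- unique(toupper(query_genes))
  if (length(query) == 0) stop("empty query gene list")
  edges <- do.call(rbind, lapply(names(tf_library), function(tf) {
    targets <- intersect(toupper(tf_library[[tf]]), query)
    if (length(targets) == 0) return(NULL)
    data.frame(source = tf, target = targets, interaction = "regulates",
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(source = character(0), target = character(0),
                        interaction = character(0), stringsAsFactors = FALSE)
  }
  tfs <- unique(edges$source)
  node_ids <- unique(c(tfs, edges$target))
  nodes <- data.frame(
    id = node_ids,
    role = ifelse(node_ids %in% tfs, "tf", "target"),
    in_query = node_ids %in% query,
    epi_class = if (is.null(epi_status)) rep(NA_character_, length(node_ids))
                else unname(epi_status[node_ids]),
    stringsAsFactors = FALSE
  )
  out_degree <- stats::setNames(integer(length(tfs)), tfs)
  if (nrow(edges) > 0) {
    tab <- table(edges$source)
    out_degree[names(tab)] <- as.integer(tab)
  }
  list(edges = edges, nodes = nodes, out_degree = out_degree)
}

#' Rank transcription factors by out-degree
#'
#' @param network network from \code{\link{build_tf_network}}.
#' @param top_k number of TFs to return (default: all).
#' @return data.frame sorted by decreasing out-degree (ties lexicographic):
#'   tf, out_degree, in_query, epi_class.
#' @export
rank_tfs_by_outdegree <- function(network, top_k = NULL) {
  if (!is.null(top_k) && top_k <= 0) stop("top_k must be positive")
  od <- network$out_degree
  if (length(od) == 0) {
    return(data.frame(tf = character(0), out_degree = integer(0),
                      in_query = logical(0), epi_class = character(0),
                      stringsAsFactors = FALSE))
  }
  ord <- order(-od, names(od))
  out <- data.frame(tf = names(od)[ord], out_degree = unname(od[ord]),
                    stringsAsFactors = FALSE)
  m <- match(out$tf, network$nodes$id)
  out$in_query <- network$nodes$in_query[m]
  out$epi_class <- network$nodes$epi_class[m]
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}
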