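test_that("BH correction equals the brute-force step-up definition", {
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(13)
  for (i in 1:25) {
    n <- sample(c(3, 10, 100, 1000), 1)
    p <- runif(n)
    expect_equal(p.adjust(p, "BH"), bh_oracle(p))
  }
})

test_that("a probe identical across tissues is a null call", {
  sheet <- toy_sheet(6)
  beta <- toy_beta(20, 6, effect = 0.3, noise = 0.02)
  beta["p0001", ] <- 0.42
  dmps <- call_dmps(beta, sheet)
  row <- dmps[dmps$probe_id == "p0001", ]
  expect_equal(row$delta_beta, 0)
  expect_equal(row$p_value, 1)
  expect_identical(row$direction, "ns")
})

test_that("DMP calling is label-symmetric", {
  sheet <- toy_sheet(8)
  beta <- toy_beta(60, 8, effect = 0.25, noise = 0.05, seed = 17)
  fwd <- call_dmps(beta, sheet)
  swapped <- sheet
  swapped$tissue <- ifelse(sheet$tissue == "tumor", "normal", "tumor")
  rev <- call_dmps(beta, swapped)
  expect_equal(rev$delta_beta, -fwd$delta_beta)
  expect_equal(rev$p_value, fwd$p_value)
  expect_identical(rev$direction[fwd$direction == "hyper"],
                   rep("hypo", sum(fwd$direction == "hyper")))
  expect_identical(rev$direction[fwd$direction == "hypo"],
                   rep("hyper", sum(fwd$direction == "hypo")))
})

test_that("region direction matches the exhaustive rule oracle", {
  for (n in 1:10) {
    for (nh in 0:n) {
      for (nl in 0:(n - nh)) {
        expect_identical(
          dmr_direction(n, nh, nl),
          dmr_rule_oracle(n, nh, nl),
          label = sprintf("n=%d nh=%d nl=%d", n, nh, nl))
      }
    }
  }
  # printed boundary: 2 of 8 probes is exactly the 25% threshold
  expect_identical(dmr_direction(8, 2, 0), "hyper")
  expect_identical(dmr_direction(8, 2, 2), "ambiguous")
  expect_identical(dmr_direction(3, 0, 0), "none")
})

test_that("region calls aggregate DMP verdicts with correct denominators", {
  dmps <- data.frame(
    probe_id = sprintf("p%d", 1:12),
    delta_beta = c(rep(0.3, 2), rep(0, 6), rep(0.3, 2), rep(-0.3, 2)),
    p_value = 0.001, q_value = 0.001,
    direction = c(rep("hyper", 2), rep("ns", 6), rep("hyper", 2),
                  rep("hypo", 2)),
    stringsAsFactors = FALSE)
  index <- list(groups = data.frame(
    gene = rep(c("GA", "GB"), c(8, 4)),
    region_group = "promoter",
    probe_id = sprintf("p%d", 1:12), stringsAsFactors = FALSE))
  out <- call_dmrs(dmps, index)
  ga <- out$full[out$full$gene == "GA", ]
  expect_equal(ga$n_probes, 8)
  expect_equal(ga$unidirectional_fraction, 0.25)
  expect_identical(ga$direction, "hyper")
  gb <- out$full[out$full$gene == "GB", ]
  expect_identical(gb$direction, "ambiguous")
  expect_false("GB" %in% out$dmrs$gene)    # mixed region excluded
  expect_true("GA" %in% out$dmrs$gene)
})

test_that("noise-free region directions recover the planted truth exactly", {
  ds <- noisefree_dataset()
  res <- run_pipeline(ds, file.path(tempdir(), "nf_run"))
  truth <- ds$truth$dmr_truth
  merged <- merge(truth, res$dmrs$full, by = c("gene", "region_group"))
  expect_equal(nrow(merged), nrow(truth))
  expect_identical(merged$direction.y, merged$direction.x)
})

test_that("CGI context summary cross-tabulates directions per class", {
  ann <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    cgi_relation = c("Island", "Island", "N_Shore",
                                     "OpenSea"),
                    stringsAsFactors = FALSE)
  dmps <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                     delta_beta = c(0.3, 0.3, 0.3, -0.3),
                     p_value = 0.001, q_value = 0.001,
                     direction = c("hyper", "hyper", "hyper", "hypo"),
                     stringsAsFactors = FALSE)
  out <- summarize_cgi_distribution(dmps, ann)
  isl <- out[out$cgi_class == "Island", ]
  expect_equal(isl$pct_hyper, 100)
  expect_equal(out[out$cgi_class == "OpenSea", "pct_hypo"], 100)

  none <- dmps
  none$direction <- "ns"
  expect_equal(nrow(summarize_cgi_distribution(none, ann)), 0)

  bad <- ann
  bad$cgi_relation[1] <- "island"   # wrong case is not a valid class
  expect_error(summarize_cgi_distribution(dmps, bad), "cgi_relation")
})

test_that("region-level verification detects strong shifts and skips nulls", {
  sheet <- toy_sheet(10)
  set.seed(23)
  # per-probe baseline shared by every sample, so null regions have
  # all-zero paired differences
  base <- runif(40, 0.3, 0.5)
  beta <- matrix(rep(base, 20), 40, 20,
                 dimnames = list(sprintf("p%04d", 1:40), sheet$sample_id))
  beta[1:4, sheet$sample_id[sheet$tissue == "tumor"]] <-
    beta[1:4, sheet$sample_id[sheet$tissue == "tumor"]] + 0.3
  index <- list(groups = data.frame(
    gene = rep(sprintf("G%02d", 1:10), each = 4),
    region_group = "promoter",
    probe_id = rownames(beta), stringsAsFactors = FALSE))
  out <- verify_dmrs_regionwise(beta, index, sheet)
  g1 <- out[out$gene == "G01", ]
  expect_true(g1$verified)
  expect_identical(g1$direction, "hyper")
  expect_gt(g1$delta_beta, 0.25)
  nulls <- out[out$gene != "G01", ]
  expect_false(any(nulls$verified))
  expect_true(all(nulls$p_value == 1))  # all-zero differences
})

test_that("patient clustering recovers planted severity groups", {
  set.seed(29)
  groups <- rep(c(0.35, 0.2, 0.05), c(5, 5, 4))
  patients <- sprintf("P%02d", seq_along(groups))
  db <- t(vapply(1:50, function(i) groups + runif(14, -0.01, 0.01),
                 numeric(14)))
  colnames(db) <- patients
  rownames(db) <- sprintf("G%02d", 1:50)
  res <- cluster_patients(db, k = 2, sub_k = 2)
  expect_equal(ari_oracle(res$labels[patients], rep(1:3, c(5, 5, 4))), 1)
  # severity order: cluster 1 is the strongest mean |change|
  expect_true(all(diff(res$summary$mean_abs_delta) <= 0))
  expect_equal(unname(unique(res$labels[patients[1:5]])), 1L)

  expect_error(cluster_patients(db, k = 20), "exceeds patient count")
  allk <- cluster_patients(db[, 1:5], k = 5, sub_k = 1)
  expect_length(unique(allk$labels), 5)

  same <- matrix(0.2, 10, 6, dimnames = list(NULL, sprintf("P%d", 1:6)))
  expect_warning(deg <- cluster_patients(same), "identical")
  expect_length(unique(deg$labels), 1)
})

test_that("per-patient promoter change matrix feeds clustering", {
  ds <- noisefree_dataset()
  beta <- compute_beta(ds$M, ds$U)
  index <- build_region_index(ds$annotation)
  dmps <- call_dmps(beta, ds$sample_sheet)
  mat <- promoter_delta_beta(beta, index, dmps, ds$sample_sheet)
  expect_equal(ncol(mat), 14)
  truth <- ds$truth$epigene_truth
  sil <- intersect(rownames(mat), truth$gene[truth$class == "silenced"])
  expect_true(all(abs(mat[sil, ] - 0.3) < 1e-9))
})

test_that("stronger planted effects never reduce DMP sensitivity", {
  sens <- function(effect, seed) {
    ds <- generate_dataset(sim_config(
      n_probes = 1500, n_genes = 60, n_pairs = 10, n_validation_tumors = 0,
      n_silenced = 8, n_overexpressed = 8, hub_degrees = c(12, 8, 6),
      delta_beta_effect = effect, n_swapped_pairs = 0, type2_bias = 1,
      seed = seed))
    beta <- compute_beta(ds$M, ds$U)
    dmps <- call_dmps(beta, ds$sample_sheet)
    truth <- ds$truth$dmp_truth
    planted <- truth$status != "null"
    mean(dmps$direction[planted] == truth$status[planted])
  }
  lo <- mean(vapply(1:3, function(s) sens(0.22, s), 0))
  hi <- mean(vapply(1:3, function(s) sens(0.35, s), 0))
  expect_gte(hi, lo)
})
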