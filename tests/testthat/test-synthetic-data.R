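test_that("config validation rejects impossible planted counts", {
  expect_error(sim_config(n_genes = 50, n_silenced = 40,
                          n_overexpressed = 20),
               "n_silenced")
  expect_error(sim_config(n_swapped_pairs = 20, n_pairs = 14),
               "n_swapped_pairs")
  expect_error(sim_config(n_probes = 300, n_genes = 100), "n_probes")
  expect_error(sim_config(frac_hyper_dmp = 1.2), "frac_hyper_dmp")
  expect_error(sim_config(hub_degrees = c(500, 53, 48)), "hub_degrees")
})

test_that("planted beta effects are exact in the zero-noise limit", {
  ds <- noisefree_dataset()
  beta <- compute_beta(ds$M, ds$U)
  expect_true(all(beta >= 0 & beta < 1))

  tissue <- ds$truth$true_tissue
  disc <- ds$sample_sheet$sample_id[ds$sample_sheet$cohort == "discovery"]
  tum <- disc[tissue[disc] == "tumor"]
  nor <- disc[tissue[disc] == "normal"]
  delta <- rowMeans(beta[, tum]) - rowMeans(beta[, nor])

  status <- ds$truth$dmp_truth$status
  expect_true(all(abs(delta[status == "hyper"] - 0.3) < 1e-12))
  expect_true(all(abs(delta[status == "hypo"] + 0.3) < 1e-12))
  expect_true(all(abs(delta[status == "null"]) < 1e-12))
})

test_that("planted silenced/overexpressed genes carry coherent effects", {
  ds <- noisefree_dataset()
  tissue <- ds$truth$true_tissue
  expr <- ds$expression
  tum <- colnames(expr)[tissue[colnames(expr)] == "tumor"]
  nor <- colnames(expr)[tissue[colnames(expr)] == "normal"]
  lfc <- log2((rowMeans(expr[, tum]) + 1) / (rowMeans(expr[, nor]) + 1))
  truth <- ds$truth$epigene_truth
  expect_true(all(lfc[truth$gene[truth$class == "silenced"]] < 0))
  expect_true(all(lfc[truth$gene[truth$class == "overexpressed"]] > 0))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_probes = 1500, n_genes = 60, n_pairs = 6,
                    n_validation_tumors = 2, n_silenced = 8,
                    n_overexpressed = 8, hub_degrees = c(12, 8, 6),
                    seed = 11)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$M, d2$M)
  expect_identical(d1$detection_p, d2$detection_p)
  expect_identical(d1$annotation, d2$annotation)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$truth, d2$truth)

  dir1 <- file.path(tempdir(), "det1")
  dir2 <- file.path(tempdir(), "det2")
  write_dataset(d1, dir1)
  write_dataset(d2, dir2)
  for (f in list.files(dir1)) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     label = f)
  }
})

test_that("annotation carries exactly the configured per-rule violations", {
  ds <- generate_dataset(sim_config(
    n_probes = 1000, n_genes = 30, n_pairs = 4, n_validation_tumors = 0,
    n_snp_probes = 50, n_sex_probes = 30, n_nonCpG_probes = 10,
    n_na_probes = 5, n_high_detp_probes = 10, n_silenced = 5,
    n_overexpressed = 5, hub_degrees = c(8, 5), seed = 3))
  ann <- ds$annotation[!duplicated(ds$annotation$probe_id), ]
  expect_equal(sum(ann$snp_within_10bp == 1), 50)
  expect_equal(sum(ann$chrom %in% c("X", "Y")), 30)
  expect_equal(sum(ann$probe_class != "cg"), 10)
  expect_equal(sum(ann$masked == 1), 5)
  rules <- ds$truth$failing_probes_by_rule
  expect_equal(sum(lengths(rules)), 50 + 30 + 10 + 5 + 10)
  # disjointness of planted rule sets
  expect_equal(anyDuplicated(unlist(rules)), 0L)
})

test_that("write/read round trip reproduces values exactly", {
  ds <- generate_dataset(sim_config(n_probes = 1200, n_genes = 40,
                                    n_pairs = 4, n_validation_tumors = 2,
                                    n_silenced = 6, n_overexpressed = 6,
                                    hub_degrees = c(8, 6), seed = 5))
  dir <- file.path(tempdir(), "roundtrip")
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(max(abs(ds$M - back$M)), 0)
  expect_equal(max(abs(ds$U - back$U)), 0)
  expect_equal(max(abs(ds$detection_p - back$detection_p)), 0)
  expect_equal(max(abs(ds$expression - back$expression)), 0)
  expect_identical(ds$annotation$gene, back$annotation$gene)
  expect_identical(ds$sample_sheet$tissue, back$sample_sheet$tissue)
  expect_identical(lapply(ds$tf_library, identity),
                   lapply(back$tf_library, identity))
})

test_that("TF target library has the configured number of sets in GMT form", {
  ds <- default_dataset()
  expect_length(ds$tf_library, 93)
  dir <- file.path(tempdir(), "gmtcheck")
  dir.create(dir, showWarnings = FALSE)
  write_gmt(ds$tf_library, file.path(dir, "tf.gmt"))
  lines <- readLines(file.path(dir, "tf.gmt"))
  expect_length(lines, 93)
  fields <- strsplit(lines, "\t")
  expect_identical(vapply(fields, `[`, "", 1), names(ds$tf_library))
  expect_true(all(lengths(fields) >= 3))
})

test_that("empty validation cohort is recorded as absent", {
  ds <- generate_dataset(sim_config(n_probes = 1000, n_genes = 30,
                                    n_pairs = 4, n_validation_tumors = 0,
                                    n_silenced = 5, n_overexpressed = 5,
                                    hub_degrees = c(8, 5), seed = 2))
  expect_false(any(ds$sample_sheet$cohort == "validation"))
  expect_equal(ncol(ds$M), 8)
  dir <- file.path(tempdir(), "novalid")
  manifest <- write_dataset(ds, dir)
  expect_equal(manifest$validation_cohort, "absent")
  expect_equal(manifest$n_validation_samples, 0)
})

test_that("sample sheet label swaps touch labels only, not data columns", {
  ds <- default_dataset()
  swapped <- ds$truth$swapped_pairs
  expect_length(swapped, 2)
  for (p in swapped) {
    rows <- ds$sample_sheet$patient_id == p
    sheet_lab <- ds$sample_sheet$tissue[rows]
    true_lab <- unname(ds$truth$true_tissue[ds$sample_sheet$sample_id[rows]])
    expect_identical(sort(sheet_lab), sort(true_lab))
    expect_false(identical(sheet_lab, true_lab))
  }
  unswapped <- setdiff(unique(ds$sample_sheet$patient_id), swapped)
  for (p in unswapped) {
    rows <- ds$sample_sheet$patient_id == p
    expect_identical(ds$sample_sheet$tissue[rows],
                     unname(ds$truth$true_tissue[
                       ds$sample_sheet$sample_id[rows]]))
  }
})
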