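test_that("identical seeds reproduce byte-identical generated files", {
  md5_of <- function(seed) {
    gen <- generate_pathway_db(n_pathways = 12, size_range = c(4, 8),
                               gene_pool_size = 120, overlap_fraction = 0.2,
                               seed = seed)
    cohort <- generate_cohort(gen$db, n_patients = 25,
                              planted = c(SP001 = 0.6), seed = seed + 1)
    tome <- generate_targetome(gen$db, seed = seed + 2)
    dir <- withr::local_tempdir()
    write_gmt(gen$db, file.path(dir, "p.gmt"))
    write_hierarchy(gen$db, file.path(dir, "h.tsv"))
    write_maf(cohort$records, file.path(dir, "m.tsv"))
    write_drug_targets(tome$records, file.path(dir, "t.tsv"))
    unname(tools::md5sum(list.files(dir, full.names = TRUE)))
  }
  expect_identical(md5_of(7), md5_of(7))
  expect_false(identical(md5_of(7), md5_of(8)))
})

test_that("generation leaves the caller's RNG stream untouched", {
  set.seed(123)
  expected <- runif(3)
  set.seed(123)
  invisible(generate_pathway_db(n_pathways = 5, size_range = c(3, 3),
                                gene_pool_size = 30, seed = 9))
  expect_identical(runif(3), expected)
})

test_that("zero overlap fraction gives pairwise disjoint memberships", {
  gen <- generate_pathway_db(n_pathways = 10, size_range = c(5, 10),
                             gene_pool_size = 200, overlap_fraction = 0,
                             seed = 51)
  all_genes <- unlist(gen$db$membership, use.names = FALSE)
  expect_false(anyDuplicated(all_genes) > 0)
  expect_equal(length(gen$db$universe), gen$truth$universe_size)
  expect_equal(length(all_genes), sum(gen$truth$sizes))
})

test_that("infeasible generator parameters are configuration errors", {
  expect_error(generate_pathway_db(size_range = c(10, 50),
                                   gene_pool_size = 20), "pool")
  expect_error(generate_pathway_db(hierarchy_depth = 0), "hierarchy_depth")
  expect_error(generate_pathway_db(n_pathways = 100, size_range = c(10, 10),
                                   gene_pool_size = 100, seed = 1),
               "exhausted")
})

test_that("generated hierarchies are acyclic with the configured depth", {
  gen <- generate_pathway_db(n_pathways = 30, size_range = c(3, 5),
                             gene_pool_size = 200, hierarchy_depth = 4,
                             seed = 52)
  # pathway_db() would have refused a cyclic hierarchy; check edge count:
  # every pathway below level 1 has exactly one parent
  expect_equal(nrow(gen$db$hierarchy), sum(gen$truth$levels > 1))
})

test_that("degenerate cohort rates behave as planted", {
  gen <- generate_pathway_db(n_pathways = 5, size_range = c(4, 4),
                             gene_pool_size = 40, seed = 61)
  none <- generate_cohort(gen$db, n_patients = 10, background_rate = 0,
                          decoy_rate = 0, seed = 62)
  expect_equal(nrow(none$records), 0L)
  expect_equal(none$truth$cohort_size, 0L)

  all_in <- generate_cohort(gen$db, n_patients = 10, background_rate = 0,
                            planted = c(SP002 = 1), decoy_rate = 0, seed = 63)
  prof <- build_aberration_profile(
    filter_mutations_by_impact(all_in$records), data_type = "mutation")
  for (p in names(prof$patient_genes)) {
    expect_setequal(prof$patient_genes[[p]], gen$db$membership$SP002)
  }
  expect_equal(prof$cohort_size, 10L)

  expect_error(generate_cohort(gen$db, background_rate = 1.5), "rates")
  expect_error(generate_cohort(gen$db, planted = c(NOPE = 0.5)),
               "not in database")
})

test_that("aberration counts match the binomial expectation", {
  gen <- generate_pathway_db(n_pathways = 25, size_range = c(20, 20),
                             gene_pool_size = 500, seed = 71)
  cohort <- generate_cohort(gen$db, n_patients = 100, background_rate = 0.02,
                            data_type = "mutation", seed = 72)
  n_cells <- 500 * 100
  expected <- n_cells * 0.02
  sd4 <- 4 * sqrt(n_cells * 0.02 * 0.98)
  expect_gt(cohort$truth$n_events, expected - sd4)
  expect_lt(cohort$truth$n_events, expected + sd4)
})

test_that("mutation mode emits included and excluded classes, truth matches post-filter", {
  gen <- generate_pathway_db(n_pathways = 10, size_range = c(10, 10),
                             gene_pool_size = 100, seed = 81)
  cohort <- generate_cohort(gen$db, n_patients = 50, background_rate = 0.05,
                            decoy_rate = 0.05, seed = 82)
  inc <- default_impact_classes()$include
  exc <- default_impact_classes()$exclude
  expect_true(any(cohort$records$variant_class %in% inc))
  expect_true(any(cohort$records$variant_class %in% exc))
  kept <- filter_mutations_by_impact(cohort$records)
  prof <- build_aberration_profile(kept, data_type = "mutation")
  got <- do.call(rbind, lapply(names(prof$patient_genes), function(p) {
    data.frame(patient_id = p, gene = prof$patient_genes[[p]],
               stringsAsFactors = FALSE)
  }))
  got <- got[order(got$patient_id, got$gene), ]
  rownames(got) <- NULL
  expect_equal(got, cohort$truth$events, ignore_attr = TRUE)
})

test_that("copy-number mode plants +/-2 calls that survive thresholding exactly", {
  gen <- generate_pathway_db(n_pathways = 10, size_range = c(10, 10),
                             gene_pool_size = 100, seed = 83)
  cohort <- generate_cohort(gen$db, n_patients = 30, background_rate = 0.05,
                            data_type = "copy_number", noise_rate = 0.1,
                            seed = 84)
  expect_true(any(abs(cohort$records$call) == 1L))
  kept <- threshold_copy_number(cohort$records)
  expect_equal(kept[c("patient_id", "gene")], cohort$truth$events,
               ignore_attr = TRUE)
})

test_that("targetome evidence-level mix matches its multinomial target", {
  gen <- generate_pathway_db(n_pathways = 200, size_range = c(5, 5),
                             gene_pool_size = 1200, seed = 91)
  tome <- generate_targetome(gen$db, fraction_pathways_targeted = 1,
                             level_mix = c(I = 0.01, II = 0.15, III = 0.84),
                             seed = 92)
  n <- nrow(tome$records)
  expect_gt(n, 300)
  for (lv in c("I", "II", "III")) {
    p <- c(I = 0.01, II = 0.15, III = 0.84)[[lv]]
    obs <- sum(tome$records$evidence_level == lv)
    expect_lt(abs(obs - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
  }
  # level III records always carry a binding value; I/II never do
  expect_false(anyNA(tome$records$assay_value_nM[
    tome$records$evidence_level == "III"]))
  expect_true(all(is.na(tome$records$assay_value_nM[
    tome$records$evidence_level != "III"])))
})

test_that("targetome fraction drives downstream light/dark truth", {
  gen <- generate_pathway_db(n_pathways = 10, size_range = c(6, 6),
                             gene_pool_size = 100, seed = 93)
  none <- generate_targetome(gen$db, fraction_pathways_targeted = 0, seed = 94)
  expect_equal(nrow(none$records), 0L)
  expect_length(none$truth$targeted_pathways, 0L)
  all_t <- generate_targetome(gen$db, fraction_pathways_targeted = 1, seed = 95)
  expect_setequal(all_t$truth$targeted_pathways, names(gen$db$membership))
})

test_that("synthetic clinical tables realize the requested stratum sizes", {
  ids <- sprintf("PT%04d", 1:200)
  cli <- generate_clinical(ids, n_positive = 57, n_negative = 118, seed = 96)
  ann <- annotate_hpv(cli)
  expect_length(hpv_positive_patients(ann), 57L)
  expect_length(hpv_negative_patients(ann), 118L)
  expect_equal(sum(ann$tier == "Unclassified"), 200L - 57L - 118L)
  expect_error(generate_clinical(ids[1:100], 57, 118), "exceeds")
})
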