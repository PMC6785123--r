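make_classification <- function(ids, labels, prop_path = NULL,
                                prop_cohort = NULL, names = ids,
                                data_type = "mutation") {
  n <- length(ids)
  data.frame(pathway_id = ids, name = names, data_type = data_type,
             label = labels,
             n_aberrant_genes = rep(1L, n),
             proportion_pathway_aberrant =
               if (is.null(prop_path)) rep(1, n) else prop_path,
             n_patients_affected = rep(1L, n),
             proportion_cohort_affected =
               if (is.null(prop_cohort)) rep(0.5, n) else prop_cohort,
             n_targets = ifelse(labels == "light", 1L, 0L),
             target_coverage_percent = 0L,
             stringsAsFactors = FALSE)
}

test_that("cohort proportion reproduces printed 8-decimal table arithmetic", {
  expect_identical(compute_cohort_proportion(180, 507), 0.35502959)
  expect_identical(compute_cohort_proportion(130, 296), 0.43918919)
  expect_identical(compute_cohort_proportion(0, 507), 0)
  expect_error(compute_cohort_proportion(1, 0), "positive")
  expect_error(compute_cohort_proportion(10, 5), "cohort_size")
})

test_that("per-pathway metrics count aberrant members and affected patients", {
  db <- tiny_db()
  rec <- data.frame(patient_id = c("P1", "P1", "P2", "P3"),
                    gene = c("A", "B", "A", "C"), stringsAsFactors = FALSE)
  prof <- build_aberration_profile(rec, data_type = "mutation")
  m <- compute_metrics("P1", db, prof)
  expect_equal(m$n_aberrant_genes, 3L)         # A, B, C all hit
  expect_equal(m$proportion_pathway_aberrant, 1)
  expect_equal(m$n_patients_affected, 3L)
  expect_equal(m$proportion_cohort_affected, 1)
  m3 <- compute_metrics("P3", db, prof)        # E, F never hit
  expect_equal(m3$n_aberrant_genes, 0L)
  expect_equal(m3$proportion_pathway_aberrant, 0)
  expect_equal(m3$n_patients_affected, 0L)
  expect_equal(m3$proportion_cohort_affected, 0)
  expect_error(compute_metrics("NOPE", db, prof), "unknown pathway")
})

test_that("classification bipartitions enriched pathways by target presence", {
  db <- tiny_db()
  rec <- data.frame(patient_id = c("P1", "P2", "P3"),
                    gene = c("A", "B", "C"), stringsAsFactors = FALSE)
  prof <- build_aberration_profile(rec, data_type = "mutation")
  enr <- enrich_pathways(prof, db, tail = "gt")  # P1 fully covered -> q = 0
  expect_true(enr$enriched[enr$pathway_id == "P1"])

  targ <- data.frame(drug = "D1", target = "A", evidence_level = "II",
                     assay_type = NA_character_, assay_value_nM = NA_real_,
                     stringsAsFactors = FALSE)
  map <- map_targets_to_pathways(summarize_targets(targ), db)
  cl <- classify_pathways(enr, map, db, prof)
  expect_equal(nrow(cl), sum(enr$enriched))
  expect_equal(cl$label[cl$pathway_id == "P1"], "light")
  expect_true(all(cl$label %in% c("light", "dark")))
  expect_equal(sum(cl$label == "light") + sum(cl$label == "dark"), nrow(cl))

  empty_map <- map_targets_to_pathways(summarize_targets(targ[0, ]), db)
  cl_dark <- classify_pathways(enr, empty_map, db, prof)
  expect_true(all(cl_dark$label == "dark"))
})

test_that("ranking sorts by pathogenicity then cohort coverage then name", {
  cl <- make_classification(
    ids = c("X", "Y", "Z", "W"),
    labels = rep("light", 4),
    prop_path = c(0.9, 1.0, 1.0, 1.0),
    prop_cohort = c(0.5, 0.1, 0.35502959, 0.35502959),
    names = c("Xray", "Yankee", "Zulu", "Whiskey"))
  ranked <- rank_pathways(cl)
  # primary key dominates: (1.0, 0.1) outranks (0.9, 0.5)
  expect_equal(ranked$pathway_id, c("W", "Z", "Y", "X"))
  expect_equal(ranked$rank, 1:4)
  # identical metrics tie-break alphabetically on display name
  expect_lt(which(ranked$pathway_id == "W"), which(ranked$pathway_id == "Z"))
})

test_that("ranking is deterministic under input permutation and per label table", {
  cl <- make_classification(
    ids = sprintf("P%02d", 1:10),
    labels = rep(c("light", "dark"), 5),
    prop_path = rep(c(1, 0.8), 5),
    prop_cohort = seq(0.1, 1, by = 0.1))
  set.seed(11)
  base <- rank_pathways(cl)
  for (rep in 1:5) {
    perm <- rank_pathways(cl[sample(nrow(cl)), , drop = FALSE])
    expect_equal(perm, base)
  }
  for (lab in c("light", "dark")) {
    expect_setequal(base$rank[base$label == lab],
                    seq_len(sum(base$label == lab)))
  }
})

test_that("data-type overlap intersects pathway IDs within matching label", {
  mut <- make_classification(c("A", "B", "C", "D"),
                             c("light", "light", "light", "dark"))
  cna <- make_classification(c("B", "C", "E", "D"),
                             c("light", "light", "light", "dark"),
                             data_type = "copy_number")
  ov <- overlap_data_types(mut, cna)
  expect_equal(ov$light_both, c("B", "C"))
  expect_equal(ov$dark_both, "D")
  expect_equal(ov$light_mut_only, "A")
  expect_equal(ov$light_cna_only, "E")
  disjoint <- overlap_data_types(make_classification("A", "light"),
                                 make_classification("B", "light"))
  expect_length(disjoint$light_both, 0L)
})

test_that("nesting walks all transitive ancestors, skipping non-enriched parents", {
  # grandparent (light) -> parent (not enriched, absent from classification)
  # -> child (dark)
  db <- pathway_db(list(GP = "g1", PAR = "g2", CH = "g3"),
                   hierarchy = data.frame(parent = c("GP", "PAR"),
                                          child = c("PAR", "CH"),
                                          stringsAsFactors = FALSE))
  cl <- make_classification(c("GP", "CH"), c("light", "dark"))
  nest <- annotate_nesting(cl, db)
  ch <- nest[nest$pathway_id == "CH", ]
  expect_true(ch$dark_under_light)
  expect_equal(ch$ancestors[[1]], c("PAR", "GP"))  # nearest-first
  gp <- nest[nest$pathway_id == "GP", ]
  expect_false(gp$dark_under_light)  # roots are never nested
  expect_equal(gp$n_ancestors, 0L)

  # no light ancestor anywhere on a 3-level chain -> FALSE
  cl2 <- make_classification(c("GP", "CH"), c("dark", "dark"))
  expect_false(any(annotate_nesting(cl2, db)$dark_under_light))
})

test_that("nesting agrees with brute-force transitive closure on random DAGs", {
  set.seed(77)
  for (rep in 1:8) {
    n <- 40
    ids <- sprintf("N%03d", 1:n)
    # random DAG: edges only from lower to higher index
    from <- sample(n - 1, 60, replace = TRUE)
    to <- pmin(n, from + sample(1:10, 60, replace = TRUE))
    keep <- to > from
    edges <- unique(data.frame(parent = ids[from[keep]],
                               child = ids[to[keep]],
                               stringsAsFactors = FALSE))
    db <- pathway_db(stats::setNames(as.list(sprintf("g%03d", 1:n)), ids),
                     hierarchy = edges)
    labels <- sample(c("light", "dark"), n, replace = TRUE)
    cl <- make_classification(ids, labels)
    nest <- annotate_nesting(cl, db)
    R <- closure_oracle(edges, ids)
    light <- ids[labels == "light"]
    for (i in seq_len(n)) {
      expected <- labels[i] == "dark" && any(R[light, ids[i]])
      expect_identical(nest$dark_under_light[i], expected)
      expect_setequal(nest$ancestors[[i]], ids[R[, ids[i]]])
    }
  }
})

test_that("partition summary computes integer percentages of the enriched set", {
  cl <- make_classification(sprintf("P%d", 1:10),
                            c(rep("light", 3), rep("dark", 7)))
  s <- summarize_partition(cl, total_pathways = 100)
  expect_equal(s$n_light, 3L)
  expect_equal(s$n_dark, 7L)
  expect_equal(s$light_percent, 30L)
  expect_equal(s$light_percent_of_total, 3L)
  zero <- summarize_partition(n_light = 0, n_enriched = 0)
  expect_equal(zero$light_percent, 0L)
  expect_equal(summarize_partition(n_light = 0, n_enriched = 10)$light_percent, 0L)
})
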