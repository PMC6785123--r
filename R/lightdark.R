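# Light/dark classification, prioritization metrics, ranking, data-type
# overlap and hierarchy nesting annotation.

#' Cohort coverage proportion
#'
#' Proportion of the cohort with at least one aberrant gene in a pathway,
#' rounded to 8 decimals (the precision used by the ranked report tables).
#'
#' @param n_patients Patients with >= 1 aberrant pathway member.
#' @param cohort_size Cohort denominator (patients with >= 1 retained
#'   aberration of the matching data type / stratum).
#' @return A proportion in [0, 1].
#' @export
compute_cohort_proportion <- function(n_patients, cohort_size) {
  if (any(cohort_size <= 0)) {
    stop("cohort_size must be positive", call. = FALSE)
  }
  if (any(n_patients < 0 | n_patients > cohort_size)) {
    stop("n_patients must lie in [0, cohort_size]", call. = FALSE)
  }
  round_half_up(n_patients / cohort_size, 8)
}

#' Pathogenicity and coverage metrics for one pathway
#'
#' @param pathway_id Pathway to measure.
#' @param db A \code{\link{pathway_db}}.
#' @param profile An aberration profile sharing the database's gene
#'   namespace.
#' @return List with \code{n_aberrant_genes},
#'   \code{proportion_pathway_aberrant} (pathway pathogenicity),
#'   \code{n_patients_affected}, \code{proportion_cohort_affected}.
#' @export
compute_metrics <- function(pathway_id, db, profile) {
  members <- db$membership[[pathway_id]]
  if (is.null(members)) {
    stop(sprintf("unknown pathway_id: %s", pathway_id), call. = FALSE)
  }
  aberrant_members <- intersect(members, names(profile$gene_patients))
  patients <- unique(unlist(profile$gene_patients[aberrant_members],
                            use.names = FALSE))
  n_pat <- length(patients)
  list(n_aberrant_genes = length(aberrant_members),
       proportion_pathway_aberrant =
         round_half_up(length(aberrant_members) / length(members), 8),
       n_patients_affected = n_pat,
       proportion_cohort_affected =
         if (profile$cohort_size > 0)
           compute_cohort_proportion(n_pat, profile$cohort_size) else 0)
}

#' Classify enriched pathways as light or dark
#'
#' An enriched pathway containing one or more drug-target genes is
#' "light" (within reach of the drug set behind the target map); an
#' enriched pathway containing none is "dark". The classification uses
#' target presence only; binding-strength and evidence-level filters are
#' reporting filters, applied to the target map before calling this if
#' desired.
#'
#' @param enrichment Data.frame from \code{\link{enrich_pathways}} (only
#'   rows with \code{enriched == TRUE} are classified).
#' @param target_map A \code{\link{map_targets_to_pathways}} result.
#' @param db A \code{\link{pathway_db}}.
#' @param profile The aberration profile the enrichment was computed from
#'   (for the prioritization metrics).
#' @return Data.frame with one row per enriched pathway: identity, label,
#'   pathogenicity and coverage metrics, target counts and rank (ranked
#'   separately within light and dark; see \code{\link{rank_pathways}}).
#' @export
classify_pathways <- function(enrichment, target_map, db, profile) {
  stopifnot(inherits(target_map, "pathway_target_map"),
            inherits(db, "pathway_db"),
            inherits(profile, "aberration_profile"))
  enr <- enrichment[enrichment$enriched, , drop = FALSE]
  if (nrow(enr) == 0L) {
    return(data.frame(pathway_id = character(0), name = character(0),
                      data_type = character(0), label = character(0),
                      n_aberrant_genes = integer(0),
                      proportion_pathway_aberrant = numeric(0),
                      n_patients_affected = integer(0),
                      proportion_cohort_affected = numeric(0),
                      n_targets = integer(0),
                      target_coverage_percent = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  metrics <- lapply(enr$pathway_id, compute_metrics, db = db,
                    profile = profile)
  n_targets <- unname(target_map$n_targets[enr$pathway_id])
  out <- data.frame(
    pathway_id = enr$pathway_id,
    name = enr$name,
    data_type = profile$data_type,
    label = ifelse(n_targets >= 1L, "light", "dark"),
    n_aberrant_genes = vapply(metrics, `[[`, integer(1), "n_aberrant_genes"),
    proportion_pathway_aberrant =
      vapply(metrics, `[[`, numeric(1), "proportion_pathway_aberrant"),
    n_patients_affected =
      vapply(metrics, `[[`, integer(1), "n_patients_affected"),
    proportion_cohort_affected =
      vapply(metrics, `[[`, numeric(1), "proportion_cohort_affected"),
    n_targets = n_targets,
    target_coverage_percent = unname(target_map$coverage[enr$pathway_id]),
    stringsAsFactors = FALSE)
  rank_pathways(out)
}

#' Rank classified pathways
#'
#' Sorts descending by pathway pathogenicity (proportion of pathway
#' aberrant), then descending by cohort coverage, then ascending by
#' display name as a deterministic tie-break, and assigns 1-based ranks
#' separately within each (data type, label) table.
#'
#' @param classifications Data.frame from \code{\link{classify_pathways}}
#'   (with or without an existing \code{rank} column).
#' @return The same rows, sorted, with \code{rank} assigned.
#' @export
rank_pathways <- function(classifications) {
  cl <- classifications
  ord <- order(-cl$proportion_pathway_aberrant,
               -cl$proportion_cohort_affected,
               cl$name, cl$pathway_id)
  cl <- cl[ord, , drop = FALSE]
  cl$rank <- stats::ave(seq_len(nrow(cl)),
                        paste(cl$data_type, cl$label, sep = "\r"),
                        FUN = seq_along)
  rownames(cl) <- NULL
  cl
}

#' Overlap of light/dark pathways between data types
#'
#' Compares classified pathway sets across mutation and copy-number runs
#' on pathway identity within matching label.
#'
#' @param mut,cna Classification data.frames for the two data types.
#' @return List with \code{light_both}, \code{dark_both},
#'   \code{light_mut_only}, \code{light_cna_only}, \code{dark_mut_only},
#'   \code{dark_cna_only} (sorted character vectors of pathway IDs).
#' @export
overlap_data_types <- function(mut, cna) {
  sets <- function(df, lab) sort(df$pathway_id[df$label == lab])
  lm <- sets(mut, "light"); lc <- sets(cna, "light")
  dm <- sets(mut, "dark");  dc <- sets(cna, "dark")
  list(light_both = intersect(lm, lc),
       dark_both = intersect(dm, dc),
       light_mut_only = setdiff(lm, lc),
       light_cna_only = setdiff(lc, lm),
       dark_mut_only = setdiff(dm, dc),
       dark_cna_only = setdiff(dc, dm))
}

# All transitive ancestors of each node in a parent->child edge list,
# memoized; returns a named list keyed by node ID. Ancestors are listed
# nearest-first (parents, then grandparents, ...), deduplicated, sorted
# within each depth level for determinism.
transitive_ancestors <- function(hierarchy, ids) {
  parents_of <- split(hierarchy$parent, hierarchy$child)
  cache <- new.env(parent = emptyenv())
  walk <- function(id) {
    hit <- mget(id, cache, ifnotfound = list(NULL))[[1]]
    if (!is.null(hit)) return(hit)
    anc <- character(0)
    frontier <- sort(unique(parents_of[[id]]))
    while (length(frontier) > 0L) {
      new <- setdiff(frontier, anc)
      anc <- c(anc, new)
      frontier <- sort(unique(unlist(parents_of[new], use.names = FALSE)))
    }
    assign(id, anc, cache)
    anc
  }
  stats::setNames(lapply(ids, walk), ids)
}

#' Annotate dark pathways nested under light ancestors
#'
#' A dark pathway can sit inside a higher-level light pathway: the
#' annotation walks ALL transitive ancestors in the hierarchy (ancestors
#' need not themselves be enriched at intermediate levels, so a dark child
#' under a non-enriched parent under a light grandparent is flagged).
#'
#' @param classifications Data.frame from \code{\link{classify_pathways}}.
#' @param db A \code{\link{pathway_db}} providing the hierarchy.
#' @return Data.frame with \code{pathway_id}, \code{label},
#'   \code{n_ancestors}, \code{ancestors} (list-column, nearest-first) and
#'   \code{dark_under_light}.
#' @export
annotate_nesting <- function(classifications, db) {
  stopifnot(inherits(db, "pathway_db"))
  ids <- classifications$pathway_id
  anc <- transitive_ancestors(db$hierarchy, ids)
  light <- classifications$pathway_id[classifications$label == "light"]
  dul <- vapply(seq_along(ids), function(i) {
    classifications$label[i] == "dark" && any(anc[[i]] %in% light)
  }, logical(1))
  data.frame(pathway_id = ids,
             label = classifications$label,
             n_ancestors = vapply(anc, length, integer(1)),
             ancestors = I(unname(anc)),
             dark_under_light = dul,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize a light/dark partition
#'
#' Reports light/dark counts and integer percentages of the enriched set,
#' and optionally of the total pathway count. Counts can be given
#' directly, or derived from a classification table.
#'
#' @param classifications Optional classification data.frame (rows are
#'   enriched pathways labelled light/dark).
#' @param n_light,n_enriched Direct counts (used when
#'   \code{classifications} is \code{NULL}).
#' @param total_pathways Optional total pathway count for
#'   whole-database percentages.
#' @return List with \code{n_light}, \code{n_dark}, \code{n_enriched},
#'   \code{light_percent}, \code{dark_percent} and, when
#'   \code{total_pathways} is given, \code{light_percent_of_total} and
#'   \code{dark_percent_of_total}. Percentages are 0 when nothing is
#'   enriched.
#' @export
summarize_partition <- function(classifications = NULL, n_light = NULL,
                                n_enriched = NULL, total_pathways = NULL) {
  if (!is.null(classifications)) {
    n_light <- sum(classifications$label == "light")
    n_enriched <- nrow(classifications)
  }
  if (is.null(n_light) || is.null(n_enriched)) {
    stop("supply either classifications or both n_light and n_enriched",
         call. = FALSE)
  }
  n_dark <- n_enriched - n_light
  pct <- function(num, den) {
    if (den == 0) 0L else as.integer(round_half_up(100 * num / den))
  }
  out <- list(n_light = n_light, n_dark = n_dark, n_enriched = n_enriched,
              light_percent = pct(n_light, n_enriched),
              dark_percent = pct(n_dark, n_enriched))
  if (!is.null(total_pathways)) {
    out$light_percent_of_total <- pct(n_light, total_pathways)
    out$dark_percent_of_total <- pct(n_dark, total_pathways)
  }
  out
}
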