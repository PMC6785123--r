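# Drug-target evidence aggregation and target-to-pathway mapping.

evidence_rank <- function(level) {
  match(level, c("I", "II", "III"))
}

#' Maximum (strongest) evidence level per target
#'
#' A target can carry multiple drug-interaction records at different
#' evidence levels (I: interaction only; II: literature support; III: at
#' least one experimental binding value); summaries use the strongest
#' level under the ordering I < II < III.
#'
#' @param records Data.frame from \code{\link{read_drug_targets}}.
#' @return Named character vector, target -> level.
#' @export
max_evidence_per_target <- function(records) {
  if (nrow(records) == 0L) return(stats::setNames(character(0), character(0)))
  lv <- tapply(evidence_rank(records$evidence_level), records$target, max)
  out <- c("I", "II", "III")[as.integer(lv)]
  stats::setNames(out, names(lv))[sort(names(lv))]
}

#' Best (minimum) binding value for a drug-target pair
#'
#' @param records Data.frame of drug-target records.
#' @param drug,target The pair to summarize.
#' @return List with \code{per_type} (named numeric, minimum per assay
#'   type) and \code{overall} (minimum across types, \code{NA} if the pair
#'   has no assay values).
#' @export
best_binding <- function(records, drug, target) {
  r <- records[records$drug == drug & records$target == target &
                 !is.na(records$assay_value_nM), , drop = FALSE]
  if (nrow(r) == 0L) {
    return(list(per_type = stats::setNames(numeric(0), character(0)),
                overall = NA_real_))
  }
  type <- ifelse(is.na(r$assay_type), "unspecified", r$assay_type)
  per_type <- tapply(r$assay_value_nM, type, min)
  per_type <- stats::setNames(as.numeric(per_type), names(per_type))
  list(per_type = per_type[sort(names(per_type))],
       overall = min(r$assay_value_nM))
}

#' Filter drug-target records by binding strength
#'
#' Keeps records whose assay value is below (strictly, by default) the
#' threshold; records without assay values are dropped while this filter
#' is active. Used for per-pathway drug listings, not for the light/dark
#' call itself.
#'
#' @param records Data.frame of drug-target records.
#' @param threshold_nM Positive threshold in nanomolar (default 1000).
#' @param strict Use \code{<} (default) rather than \code{<=}.
#' @return The retained records.
#' @export
filter_by_binding <- function(records, threshold_nM = 1000, strict = TRUE) {
  if (!(is.numeric(threshold_nM) && length(threshold_nM) == 1L &&
        threshold_nM > 0)) {
    stop("threshold_nM must be a single positive value", call. = FALSE)
  }
  v <- records$assay_value_nM
  keep <- !is.na(v) & (if (strict) v < threshold_nM else v <= threshold_nM)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize drug-target records per target
#'
#' @param records Data.frame of drug-target records.
#' @return Data.frame with one row per target: \code{target},
#'   \code{max_evidence_level}, \code{best_binding_nM} (minimum present
#'   assay value, \code{NA} if none) and a list-column \code{drugs}.
#' @export
summarize_targets <- function(records) {
  targets <- sort(unique(records$target))
  if (length(targets) == 0L) {
    return(data.frame(target = character(0),
                      max_evidence_level = character(0),
                      best_binding_nM = numeric(0),
                      drugs = I(list()), stringsAsFactors = FALSE))
  }
  max_lv <- max_evidence_per_target(records)
  best <- vapply(targets, function(t) {
    v <- records$assay_value_nM[records$target == t]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else min(v)
  }, numeric(1))
  drugs <- lapply(targets, function(t) {
    sort(unique(records$drug[records$target == t]))
  })
  data.frame(target = targets,
             max_evidence_level = unname(max_lv[targets]),
             best_binding_nM = unname(best),
             drugs = I(drugs), stringsAsFactors = FALSE, row.names = NULL)
}

#' Map drug targets onto pathways
#'
#' Intersects the (optionally filtered) target set with each pathway's
#' member genes and computes per-pathway target coverage as an integer
#' percentage of pathway size (rounded half away from zero, so 4 targets
#' in a 22-gene pathway give 18 percent).
#'
#' @param summaries Output of \code{\link{summarize_targets}}; target
#'   symbols must share the pathway database's namespace (normalize
#'   first).
#' @param db A \code{\link{pathway_db}}.
#' @param min_level Optional evidence-level floor ("I", "II" or "III").
#' @param binding_threshold Optional nM cutoff applied to the per-target
#'   best binding value (strict \code{<}; targets without values drop).
#' @return Object of class \code{pathway_target_map}: list with
#'   \code{targets} (pathway -> character vector), \code{coverage}
#'   (pathway -> integer percent), \code{n_targets}, and the filtered
#'   \code{summaries}.
#' @export
map_targets_to_pathways <- function(summaries, db, min_level = NULL,
                                    binding_threshold = NULL) {
  stopifnot(inherits(db, "pathway_db"))
  s <- summaries
  if (!is.null(min_level)) {
    if (!(min_level %in% c("I", "II", "III"))) {
      stop("min_level must be one of I, II, III", call. = FALSE)
    }
    s <- s[evidence_rank(s$max_evidence_level) >= evidence_rank(min_level), ,
           drop = FALSE]
  }
  if (!is.null(binding_threshold)) {
    s <- s[!is.na(s$best_binding_nM) & s$best_binding_nM < binding_threshold, ,
           drop = FALSE]
  }
  target_set <- s$target
  targets <- lapply(db$membership, function(g) intersect(g, target_set))
  n_targets <- vapply(targets, length, integer(1))
  m <- vapply(db$membership, length, integer(1))
  coverage <- as.integer(round_half_up(100 * n_targets / m))
  structure(list(targets = targets,
                 coverage = stats::setNames(coverage, names(db$membership)),
                 n_targets = stats::setNames(n_targets, names(db$membership)),
                 summaries = s),
            class = "pathway_target_map")
}

#' Per-pathway drug report
#'
#' Lists, for each pathway, the targeted member genes and the drugs that
#' hit them, with maximum evidence level and best binding value per
#' drug-target pair (mirroring a drug-target table restricted to pathway
#' members).
#'
#' @param records Drug-target records (optionally pre-filtered, e.g. with
#'   \code{\link{filter_by_binding}}).
#' @param db A \code{\link{pathway_db}}.
#' @param pathway_ids Pathways to report on (default: all).
#' @return Data.frame with columns \code{pathway_id}, \code{target},
#'   \code{drug}, \code{max_evidence_level}, \code{assay_type},
#'   \code{best_value_nM}.
#' @export
pathway_drug_report <- function(records, db, pathway_ids = names(db$membership)) {
  max_lv <- max_evidence_per_target(records)
  rows <- list()
  for (pid in pathway_ids) {
    members <- db$membership[[pid]]
    if (is.null(members)) stop(sprintf("unknown pathway_id: %s", pid),
                               call. = FALSE)
    r <- records[records$target %in% members, , drop = FALSE]
    if (nrow(r) == 0L) next
    pairs <- unique(r[c("target", "drug")])
    pairs <- pairs[order(pairs$target, pairs$drug), , drop = FALSE]
    for (i in seq_len(nrow(pairs))) {
      bb <- best_binding(r, pairs$drug[i], pairs$target[i])
      best_type <- if (length(bb$per_type) == 0L) NA_character_ else
        names(bb$per_type)[which.min(bb$per_type)]
      rows[[length(rows) + 1L]] <- data.frame(
        pathway_id = pid, target = pairs$target[i], drug = pairs$drug[i],
        max_evidence_level = unname(max_lv[pairs$target[i]]),
        assay_type = best_type, best_value_nM = bb$overall,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(pathway_id = character(0), target = character(0),
                      drug = character(0), max_evidence_level = character(0),
                      assay_type = character(0), best_value_nM = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
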