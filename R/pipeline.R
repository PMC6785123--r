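# Pipeline orchestration: read inputs, filter, profile, enrich, classify,
# rank, compare data types, annotate nesting, and emit ranked TSV reports
# plus a run manifest.

#' Build a validated run configuration
#'
#' @param mutations Path to a MAF-like mutation TSV (optional).
#' @param copy_number Path to a GISTIC-thresholded matrix TSV (optional;
#'   at least one of the two data types is required).
#' @param pathways Path to pathway membership (GMT or TSV).
#' @param hierarchy Optional path to the parent-child hierarchy TSV.
#' @param drug_targets Optional path to the drug-target TSV (without it,
#'   every enriched pathway classifies dark).
#' @param clinical Optional path to the clinical/HPV TSV; when present the
#'   mutation analysis is rerun for the HPV-positive and HPV-negative
#'   strata.
#' @param symbol_map Optional path to an alias-approved synonym TSV.
#' @param out_dir Output directory for reports (created if needed).
#' @param alpha FDR threshold (default 0.05).
#' @param tail Hypergeometric tail convention, \code{"ge"} or \code{"gt"}.
#' @param binding_threshold_nM Binding cutoff for the per-pathway drug
#'   report (default 1000; the light/dark call itself is unfiltered).
#' @param min_evidence_level Optional evidence floor for the light/dark
#'   target map (default none).
#' @param include,exclude Variant-impact class lists.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(mutations = NULL, copy_number = NULL, pathways,
                       hierarchy = NULL, drug_targets = NULL, clinical = NULL,
                       symbol_map = NULL, out_dir = tempfile("pathlight_run_"),
                       alpha = 0.05, tail = c("ge", "gt"),
                       binding_threshold_nM = 1000,
                       min_evidence_level = NULL,
                       include = default_impact_classes()$include,
                       exclude = default_impact_classes()$exclude) {
  tail <- match.arg(tail)
  if (is.null(mutations) && is.null(copy_number)) {
    stop("at least one of mutations / copy_number inputs is required",
         call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  if (binding_threshold_nM <= 0) {
    stop("binding_threshold_nM must be positive", call. = FALSE)
  }
  if (length(intersect(include, exclude)) > 0L) {
    stop("include and exclude class lists overlap", call. = FALSE)
  }
  structure(list(mutations = mutations, copy_number = copy_number,
                 pathways = pathways, hierarchy = hierarchy,
                 drug_targets = drug_targets, clinical = clinical,
                 symbol_map = symbol_map, out_dir = out_dir, alpha = alpha,
                 tail = tail, binding_threshold_nM = binding_threshold_nM,
                 min_evidence_level = min_evidence_level,
                 include = include, exclude = exclude),
            class = "run_config")
}

# Format classification tables for TSV emission (proportions already
# rounded to 8 decimals by compute_metrics).
format_classification <- function(cl) {
  cl$proportion_pathway_aberrant <-
    format(cl$proportion_pathway_aberrant, trim = TRUE, scientific = FALSE)
  cl$proportion_cohort_affected <-
    format(cl$proportion_cohort_affected, trim = TRUE, scientific = FALSE)
  cl
}

run_stage <- function(tag, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", tag, conditionMessage(e)), call. = FALSE)
  })
}

analyse_profile <- function(profile, db, target_map, config, stratum,
                            drug_records, out_dir) {
  prefix <- paste0(profile$data_type,
                   if (nzchar(stratum)) paste0("_", stratum) else "")
  enr <- enrich_pathways(profile, db, alpha = config$alpha,
                         tail = config$tail)
  cl <- classify_pathways(enr, target_map, db, profile)
  nest <- annotate_nesting(cl, db)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(prefix, "_", name, ".tsv"))
    write_tsv(df, path)
    files <<- c(files, basename(path))
  }
  emit(enr, "enrichment")
  emit(format_classification(cl[cl$label == "light", , drop = FALSE]), "light")
  emit(format_classification(cl[cl$label == "dark", , drop = FALSE]), "dark")
  nest_tsv <- nest
  nest_tsv$ancestors <- vapply(nest$ancestors, paste, character(1),
                               collapse = ";")
  emit(nest_tsv, "nesting")
  if (!is.null(drug_records) && nrow(cl) > 0L) {
    filtered <- filter_by_binding(drug_records,
                                  threshold_nM = config$binding_threshold_nM)
    emit(pathway_drug_report(filtered, db, cl$pathway_id), "drug_report")
  }
  list(enrichment = enr, classification = cl, nesting = nest,
       summary = summarize_partition(cl,
                                     total_pathways = length(db$membership)),
       files = files)
}

#' Run the full light/dark pathway pipeline
#'
#' Reads all configured inputs, normalizes gene symbols, applies the
#' variant-impact and copy-number filters, builds per-patient aberration
#' profiles, tests every pathway for over-representation, classifies
#' enriched pathways light/dark against the drug-target table, ranks them
#' by pathogenicity and cohort coverage, annotates hierarchy nesting,
#' compares data types, optionally reruns the mutation analysis per HPV
#' stratum, and writes ranked TSV reports plus a JSON manifest (config,
#' input file MD5 hashes, package version, output list) to the output
#' directory.
#'
#' @param config A \code{\link{run_config}}.
#' @return Invisibly, a list with per-data-type (and per-stratum) results
#'   (\code{enrichment}, \code{classification}, \code{nesting},
#'   \code{summary}), the \code{overlap} between data types when both are
#'   present, and \code{manifest}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  db <- run_stage("pathways", read_pathways(config$pathways, config$hierarchy))
  smap <- if (!is.null(config$symbol_map)) {
    run_stage("symbol_map", read_symbol_map(config$symbol_map))
  }
  norm <- function(genes) {
    if (is.null(smap)) NULL else normalize_gene_symbols(genes, smap)$mapped
  }

  target_map <- if (!is.null(config$drug_targets)) {
    run_stage("drug_targets", {
      rec <- read_drug_targets(config$drug_targets)
      if (!is.null(smap)) {
        nm <- normalize_gene_symbols(rec$target, smap)
        if (length(nm$unmapped) > 0L) {
          message(sprintf("%d drug target(s) failed symbol normalization; excluded",
                          length(nm$unmapped)))
          rec <- rec[!(rec$target %in% nm$unmapped), , drop = FALSE]
        }
        rec$target <- unname(nm$mapped[rec$target])
      }
      map_targets_to_pathways(summarize_targets(rec), db,
                              min_level = config$min_evidence_level)
    })
  } else {
    map_targets_to_pathways(summarize_targets(
      data.frame(drug = character(0), target = character(0),
                 evidence_level = character(0), assay_type = character(0),
                 assay_value_nM = numeric(0), stringsAsFactors = FALSE)), db)
  }
  drug_records <- if (!is.null(config$drug_targets)) {
    read_drug_targets(config$drug_targets)
  }

  results <- list()
  all_files <- character(0)

  mut_profile <- NULL
  if (!is.null(config$mutations)) {
    mut_profile <- run_stage("mutations", {
      rec <- read_mutations(config$mutations)
      rec <- filter_mutations_by_impact(rec, config$include, config$exclude)
      build_aberration_profile(rec, norm(rec$gene), "mutation")
    })
    results$mutation <- analyse_profile(mut_profile, db, target_map, config,
                                        "", drug_records, config$out_dir)
    all_files <- c(all_files, results$mutation$files)
  }
  if (!is.null(config$copy_number)) {
    cna_profile <- run_stage("copy_number", {
      rec <- read_copy_number(config$copy_number)
      rec <- threshold_copy_number(rec)
      build_aberration_profile(rec, norm(rec$gene), "copy_number")
    })
    results$copy_number <- analyse_profile(cna_profile, db, target_map,
                                           config, "", drug_records,
                                           config$out_dir)
    all_files <- c(all_files, results$copy_number$files)
  }
  if (!is.null(results$mutation) && !is.null(results$copy_number)) {
    ov <- overlap_data_types(results$mutation$classification,
                             results$copy_number$classification)
    ov_df <- data.frame(set = names(ov),
                        n = vapply(ov, length, integer(1)),
                        pathway_ids = vapply(ov, paste, character(1),
                                             collapse = ";"),
                        stringsAsFactors = FALSE)
    write_tsv(ov_df, file.path(config$out_dir, "overlap.tsv"))
    all_files <- c(all_files, "overlap.tsv")
    results$overlap <- ov
  }
  if (!is.null(config$clinical) && !is.null(mut_profile)) {
    ann <- run_stage("clinical", {
      cli <- read_tsv_checked(config$clinical,
                              c("patient_id", "nulton_call", "wgs_available",
                                "tcga_clinical_call", "tcga_nature_call"))
      annotate_hpv(cli)
    })
    strata <- list(hpv_positive = hpv_positive_patients(ann),
                   hpv_negative = hpv_negative_patients(ann))
    for (sname in names(strata)) {
      ids <- intersect(strata[[sname]], names(mut_profile$patient_genes))
      if (length(ids) == 0L) {
        message(sprintf("stratum %s shares no patients with the mutation cohort; skipped",
                        sname))
        next
      }
      sp <- stratify_profile(mut_profile, ids)
      results[[sname]] <- analyse_profile(sp, db, target_map, config, sname,
                                          drug_records, config$out_dir)
      all_files <- c(all_files, results[[sname]]$files)
    }
  }

  inputs <- Filter(Negate(is.null),
                   config[c("mutations", "copy_number", "pathways",
                            "hierarchy", "drug_targets", "clinical",
                            "symbol_map")])
  manifest <- list(
    tool = "pathlight",
    version = as.character(utils::packageVersion("pathlight")),
    config = list(alpha = config$alpha, tail = config$tail,
                  binding_threshold_nM = config$binding_threshold_nM,
                  min_evidence_level = config$min_evidence_level,
                  include = config$include, exclude = config$exclude),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = sort(unique(all_files)))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
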