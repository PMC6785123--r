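#' Default variant-impact include/exclude lists
#'
#' High- and moderate-impact variant classes are retained (missense,
#' nonsense, nonstop, frameshift and in-frame indels, splice site,
#' translation start site); low/modifier-impact classes (UTRs, flanks,
#' intronic, intergenic, RNA, silent, splice region) are excluded. Tokens
#' follow the MAF Variant_Classification vocabulary.
#'
#' @return List with character vectors \code{include} and \code{exclude}.
#' @export
default_impact_classes <- function() {
  list(
    include = c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
                "Frame_Shift_Del", "Frame_Shift_Ins",
                "In_Frame_Del", "In_Frame_Ins",
                "Splice_Site", "Translation_Start_Site"),
    exclude = c("3'Flank", "3'UTR", "5'Flank", "5'UTR", "IGR", "Intron",
                "RNA", "Silent", "Splice_Region")
  )
}

#' Filter mutation records by variant impact class
#'
#' Keeps exactly the records whose variant classification is in the include
#' list. Records with classes in neither list (vocabulary drift across MAF
#' releases) are dropped with a warning rather than an error.
#'
#' @param records Data.frame from \code{\link{read_mutations}}.
#' @param include,exclude Character vectors of variant classes; must be
#'   disjoint. Defaults from \code{\link{default_impact_classes}}.
#' @return The retained records.
#' @export
filter_mutations_by_impact <- function(records,
                                       include = default_impact_classes()$include,
                                       exclude = default_impact_classes()$exclude) {
  overlap <- intersect(include, exclude)
  if (length(overlap) > 0L) {
    stop(sprintf("include and exclude class lists overlap: %s",
                 paste(overlap, collapse = ", ")), call. = FALSE)
  }
  known <- records$variant_class %in% c(include, exclude)
  if (any(!known)) {
    warning(sprintf("dropping %d record(s) with variant class in neither list: %s",
                    sum(!known),
                    paste(utils::head(unique(records$variant_class[!known]), 5L),
                          collapse = ", ")), call. = FALSE)
  }
  out <- records[records$variant_class %in% include, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only high-confidence copy-number calls
#'
#' Retains calls of -2 and +2 (high-confidence deletions and
#' amplifications). Amplifications and deletions are treated identically
#' downstream: the profile keeps only "altered" status, not the sign.
#'
#' @param records Data.frame from \code{\link{read_copy_number}}.
#' @return The retained records.
#' @export
threshold_copy_number <- function(records) {
  out <- records[abs(records$call) == 2L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a per-patient aberration profile
#'
#' Aggregates filtered mutation or copy-number records into per-patient
#' sets of aberrant gene symbols, with the transposed gene-to-patients map
#' kept consistent. Cohort size counts patients with at least one retained
#' aberration, which is the denominator used by the cohort-coverage
#' metrics.
#'
#' @param records Data.frame with columns \code{patient_id} and
#'   \code{gene} (already filtered).
#' @param symbol_mapping Optional named character vector (raw -> approved)
#'   from \code{\link{normalize_gene_symbols}}; genes present in the map
#'   are renamed, others are kept as-is.
#' @param data_type \code{"mutation"} or \code{"copy_number"}.
#' @return An object of class \code{aberration_profile}: list with
#'   \code{data_type}, \code{patient_genes}, \code{gene_patients},
#'   \code{cohort_size}.
#' @export
build_aberration_profile <- function(records, symbol_mapping = NULL,
                                     data_type = c("mutation", "copy_number")) {
  data_type <- match.arg(data_type)
  genes <- records$gene
  if (!is.null(symbol_mapping) && length(symbol_mapping) > 0L) {
    hit <- genes %in% names(symbol_mapping)
    genes[hit] <- unname(symbol_mapping[genes[hit]])
  }
  patient_genes <- lapply(split(genes, records$patient_id),
                          function(g) sort(unique(g)))
  patient_genes <- patient_genes[vapply(patient_genes, length, integer(1)) > 0L]
  gene_patients <- transpose_sets(patient_genes)
  structure(list(data_type = data_type,
                 patient_genes = patient_genes,
                 gene_patients = gene_patients,
                 cohort_size = length(patient_genes)),
            class = "aberration_profile")
}

# Transpose a named list of sets: names(x) grouped by element value.
transpose_sets <- function(x) {
  if (length(x) == 0L) return(list())
  key <- rep(names(x), vapply(x, length, integer(1)))
  val <- unlist(x, use.names = FALSE)
  lapply(split(key, val), function(p) sort(unique(p)))
}

#' @export
print.aberration_profile <- function(x, ...) {
  cat(sprintf("aberration_profile (%s): %d patients, %d aberrant genes\n",
              x$data_type, x$cohort_size, length(x$gene_patients)))
  invisible(x)
}

#' Restrict an aberration profile to a patient subset
#'
#' Used for stratified reruns (e.g. HPV-positive vs HPV-negative). IDs not
#' present in the profile are logged and ignored; an empty intersection is
#' an error. The transpose maps and cohort size are recomputed.
#'
#' @param profile An \code{aberration_profile}.
#' @param patient_ids Character vector of patient IDs to keep.
#' @return A restricted \code{aberration_profile}.
#' @export
stratify_profile <- function(profile, patient_ids) {
  stopifnot(inherits(profile, "aberration_profile"))
  extra <- setdiff(patient_ids, names(profile$patient_genes))
  if (length(extra) > 0L) {
    message(sprintf("%d stratum patient ID(s) not in profile; ignored",
                    length(extra)))
  }
  keep <- intersect(names(profile$patient_genes), patient_ids)
  if (length(keep) == 0L) {
    stop("stratum shares no patients with the profile", call. = FALSE)
  }
  pg <- profile$patient_genes[keep]
  structure(list(data_type = profile$data_type,
                 patient_genes = pg,
                 gene_patients = transpose_sets(pg),
                 cohort_size = length(pg)),
            class = "aberration_profile")
}

#' Assign HPV tumor-status confidence tiers
#'
#' Combines three annotation sources into a deterministic confidence tier,
#' taking the RNA/WGS-based call (the \code{nulton_call} column) as
#' primary:
#' \itemize{
#'   \item positive with whole-genome sequencing available, or positive and
#'     corroborated by either TCGA source: \code{HighestConfidencePositive};
#'   \item positive with no WGS and no corroboration:
#'     \code{HighConfidencePositive};
#'   \item negative with WGS available: \code{HighConfidenceNegative};
#'   \item anything else: \code{Unclassified}.
#' }
#' Downstream stratification treats only \code{HighestConfidencePositive}
#' as HPV-positive and \code{HighConfidenceNegative} as HPV-negative.
#'
#' @param annotations Data.frame with columns \code{patient_id},
#'   \code{nulton_call}, \code{wgs_available} (logical or "true"/"false"),
#'   \code{tcga_clinical_call}, \code{tcga_nature_call}; calls are
#'   \code{"positive"}, \code{"negative"} or \code{"unknown"}.
#' @return The input with a \code{tier} column appended.
#' @export
annotate_hpv <- function(annotations) {
  req <- c("patient_id", "nulton_call", "wgs_available",
           "tcga_clinical_call", "tcga_nature_call")
  missing <- setdiff(req, names(annotations))
  if (length(missing) > 0L) {
    stop(sprintf("missing HPV annotation column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ann <- annotations
  ann$wgs_available <- as_logical_flag(ann$wgs_available)
  for (col in c("nulton_call", "tcga_clinical_call", "tcga_nature_call")) {
    ann[[col]] <- tolower(chr_trim(ann[[col]]))
    bad <- !(ann[[col]] %in% c("positive", "negative", "unknown"))
    if (any(bad)) {
      stop(sprintf("invalid %s value(s): %s", col,
                   paste(unique(ann[[col]][bad]), collapse = ", ")),
           call. = FALSE)
    }
  }
  if (anyDuplicated(ann$patient_id)) {
    dup_ids <- unique(ann$patient_id[duplicated(ann$patient_id)])
    key <- do.call(paste, c(ann[req], sep = "\r"))
    contradictory <- dup_ids[vapply(dup_ids, function(id) {
      length(unique(key[ann$patient_id == id])) > 1L
    }, logical(1))]
    if (length(contradictory) > 0L) {
      stop(sprintf("contradictory duplicate HPV rows for patient(s): %s",
                   paste(utils::head(contradictory, 5L), collapse = ", ")),
           call. = FALSE)
    }
    ann <- ann[!duplicated(ann$patient_id), , drop = FALSE]
  }
  corroborated <- ann$tcga_clinical_call == "positive" |
    ann$tcga_nature_call == "positive"
  tier <- rep("Unclassified", nrow(ann))
  tier[ann$nulton_call == "positive" & (ann$wgs_available | corroborated)] <-
    "HighestConfidencePositive"
  tier[ann$nulton_call == "positive" & !ann$wgs_available & !corroborated] <-
    "HighConfidencePositive"
  tier[ann$nulton_call == "negative" & ann$wgs_available] <-
    "HighConfidenceNegative"
  ann$tier <- tier
  rownames(ann) <- NULL
  ann
}

as_logical_flag <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(chr_trim(x))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out)) {
    stop("wgs_available must be logical (true/false)", call. = FALSE)
  }
  out
}

#' Patient IDs called HPV-positive / HPV-negative for stratification
#'
#' @param annotations Output of \code{\link{annotate_hpv}}.
#' @return Character vector of patient IDs.
#' @export
hpv_positive_patients <- function(annotations) {
  annotations$patient_id[annotations$tier == "HighestConfidencePositive"]
}

#' @rdname hpv_positive_patients
#' @export
hpv_negative_patients <- function(annotations) {
  annotations$patient_id[annotations$tier == "HighConfidenceNegative"]
}

#' Collapse raw anatomic-site annotations into three categories
#'
#' Oral cavity (alveolar ridge, buccal mucosa, floor of mouth, hard palate,
#' hypopharynx, lip, oral cavity, oral tongue), oropharynx (base of tongue,
#' tonsil) and larynx; anything unrecognized maps to \code{"Unknown"} with
#' a message. Matching is case-insensitive on trimmed input.
#'
#' @param raw_site Character vector of raw anatomic subdivision labels.
#' @return Character vector with values \code{"OralCavity"},
#'   \code{"Oropharynx"}, \code{"Larynx"} or \code{"Unknown"}.
#' @export
collapse_anatomic_site <- function(raw_site) {
  oral <- c("alveolar ridge", "buccal mucosa", "floor of mouth",
            "hard palate", "hypopharynx", "lip", "oral cavity", "oral tongue")
  oroph <- c("base of tongue", "tonsil")
  v <- tolower(chr_trim(raw_site))
  out <- rep("Unknown", length(v))
  out[v %in% oral] <- "OralCavity"
  out[v %in% oroph] <- "Oropharynx"
  out[v == "larynx"] <- "Larynx"
  if (any(out == "Unknown" & nzchar(v))) {
    message(sprintf("%d anatomic site value(s) not recognized; set to Unknown",
                    sum(out == "Unknown" & nzchar(v))))
  }
  out
}
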