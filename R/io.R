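#' Read a MAF-like somatic mutation table
#'
#' Parses the three columns of a Mutation Annotation Format (MAF) style
#' tab-separated file that the pathway analysis consumes: sample barcode,
#' gene symbol and variant classification. Column names are configurable
#' because GDC MAF dialects vary; defaults follow the standard MAF header.
#'
#' Duplicate (patient, gene, classification) rows are preserved here;
#' deduplication into per-patient gene sets happens when the aberration
#' profile is built.
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @param columns Named list mapping the roles \code{patient}, \code{gene}
#'   and \code{class} to column names in the file.
#' @param barcode_fields If not \code{NULL}, truncate the sample barcode to
#'   this many dash-separated fields to obtain the patient ID (e.g. 3 turns
#'   \code{TCGA-XX-1234-01A} into \code{TCGA-XX-1234}). Default keeps the
#'   full barcode.
#' @param lenient If \code{TRUE} (default), rows with empty patient or gene
#'   fields are dropped with a message; if \code{FALSE} they are an error.
#' @return A data.frame with columns \code{patient_id}, \code{gene},
#'   \code{variant_class}, one row per retained input row.
#' @export
read_mutations <- function(path,
                           columns = list(patient = "Tumor_Sample_Barcode",
                                          gene = "Hugo_Symbol",
                                          class = "Variant_Classification"),
                           barcode_fields = NULL,
                           lenient = TRUE) {
  stopifnot(all(c("patient", "gene", "class") %in% names(columns)))
  df <- read_tsv_checked(path, unlist(columns))
  if (nrow(df) == 0L) {
    stop(sprintf("no data rows in mutation file: %s", path), call. = FALSE)
  }
  out <- data.frame(patient_id = chr_trim(df[[columns$patient]]),
                    gene = chr_trim(df[[columns$gene]]),
                    variant_class = chr_trim(df[[columns$class]]),
                    stringsAsFactors = FALSE)
  if (!is.null(barcode_fields)) {
    parts <- strsplit(out$patient_id, "-", fixed = TRUE)
    out$patient_id <- vapply(parts, function(p) {
      paste(p[seq_len(min(length(p), barcode_fields))], collapse = "-")
    }, character(1))
  }
  bad <- out$patient_id == "" | out$gene == ""
  if (any(bad)) {
    if (!lenient) {
      stop(sprintf("%d mutation row(s) with empty patient or gene field",
                   sum(bad)), call. = FALSE)
    }
    message(sprintf("dropping %d mutation row(s) with empty patient or gene field",
                    sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read a GISTIC-thresholded gene-by-sample copy-number matrix
#'
#' The first column holds gene symbols, the remaining columns one sample
#' each; cells are thresholded integer calls in \{-2, -1, 0, 1, 2\} where
#' -2/+2 denote high-confidence deletion/amplification. No thresholding is
#' applied here; see \code{\link{threshold_copy_number}}.
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @return A data.frame with columns \code{patient_id}, \code{gene},
#'   \code{call} (integer), one row per matrix cell.
#' @export
read_copy_number <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  if (ncol(df) < 2L || nrow(df) == 0L) {
    stop(sprintf("copy-number matrix needs >=1 gene row and >=1 sample column: %s",
                 path), call. = FALSE)
  }
  genes <- chr_trim(df[[1L]])
  samples <- names(df)[-1L]
  vals <- suppressWarnings(
    vapply(df[-1L], function(col) as.numeric(chr_trim(col)), numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df))
  bad <- which(is.na(vals) | vals != round(vals) | abs(vals) > 2,
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "invalid copy-number call at gene '%s', sample '%s' (must be integer in -2..2)",
      genes[bad[1L, 1L]], samples[bad[1L, 2L]]), call. = FALSE)
  }
  data.frame(patient_id = rep(samples, each = length(genes)),
             gene = rep(genes, times = length(samples)),
             call = as.integer(vals),
             stringsAsFactors = FALSE)
}

#' Construct and validate a pathway database
#'
#' A pathway database holds pathway gene membership, display names, an
#' optional acyclic parent-to-child hierarchy, and the gene universe (the
#' union of all membership sets), which is the population of the
#' over-representation test.
#'
#' @param membership Named list: pathway ID to character vector of member
#'   gene symbols (non-empty).
#' @param names Optional named character vector of display names; defaults
#'   to the pathway IDs.
#' @param hierarchy Optional data.frame with columns \code{parent},
#'   \code{child} referencing pathway IDs in \code{membership}.
#' @return An object of class \code{pathway_db} with elements
#'   \code{membership}, \code{names}, \code{hierarchy}, \code{universe}.
#' @export
pathway_db <- function(membership, names = NULL, hierarchy = NULL) {
  if (length(membership) == 0L || is.null(base::names(membership))) {
    stop("membership must be a non-empty named list", call. = FALSE)
  }
  membership <- lapply(membership, function(g) sort(unique(chr_trim(g))))
  empty <- vapply(membership, length, integer(1)) == 0L
  if (any(empty)) {
    stop(sprintf("pathway(s) with empty membership: %s",
                 paste(base::names(membership)[empty], collapse = ", ")),
         call. = FALSE)
  }
  ids <- base::names(membership)
  if (anyDuplicated(ids)) {
    stop("duplicate pathway IDs in membership", call. = FALSE)
  }
  if (is.null(names)) {
    names <- stats::setNames(ids, ids)
  } else {
    names <- stats::setNames(as.character(names[ids]), ids)
    names[is.na(names)] <- ids[is.na(names)]
  }
  if (is.null(hierarchy)) {
    hierarchy <- data.frame(parent = character(0), child = character(0),
                            stringsAsFactors = FALSE)
  } else {
    hierarchy <- data.frame(parent = as.character(hierarchy$parent),
                            child = as.character(hierarchy$child),
                            stringsAsFactors = FALSE)
    unknown <- setdiff(unique(c(hierarchy$parent, hierarchy$child)), ids)
    if (length(unknown) > 0L) {
      stop(sprintf("hierarchy references unknown pathway ID(s): %s",
                   paste(utils::head(unknown, 5L), collapse = ", ")),
           call. = FALSE)
    }
    cyc <- find_cycle(hierarchy)
    if (!is.null(cyc)) {
      stop(sprintf("pathway hierarchy contains a cycle: %s",
                   paste(cyc, collapse = " -> ")), call. = FALSE)
    }
  }
  structure(list(membership = membership,
                 names = names,
                 hierarchy = hierarchy,
                 universe = sort(unique(unlist(membership, use.names = FALSE)))),
            class = "pathway_db")
}

# Return one cycle (vector of node IDs) from a parent->child edge list, or
# NULL if the graph is acyclic. Iterative DFS with colouring.
find_cycle <- function(edges) {
  if (nrow(edges) == 0L) return(NULL)
  children <- split(edges$child, edges$parent)
  colour <- new.env(parent = emptyenv())
  path <- character(0)
  found <- NULL
  visit <- function(node) {
    if (!is.null(found)) return()
    state <- mget(node, colour, ifnotfound = "white")[[1]]
    if (state == "grey") {
      found <<- c(path[which(path == node)[1]:length(path)], node)
      return()
    }
    if (state == "black") return()
    assign(node, "grey", colour)
    path <<- c(path, node)
    for (ch in children[[node]]) visit(ch)
    path <<- path[-length(path)]
    assign(node, "black", colour)
  }
  for (n in unique(edges$parent)) {
    visit(n)
    if (!is.null(found)) return(found)
  }
  NULL
}

#' Read pathway membership (GMT or two-column TSV) plus optional hierarchy
#'
#' GMT lines are \code{id<TAB>description<TAB>gene1<TAB>gene2...}; the
#' two-column TSV format has a header row and columns \code{pathway_id},
#' \code{gene}. The hierarchy file is a headered two-column TSV
#' (\code{parent<TAB>child}). In lenient mode hierarchy rows referencing
#' unknown pathways are dropped with a message; in strict mode they are an
#' error. A cyclic hierarchy is always an error.
#'
#' @param membership_path Path to GMT or pathway-gene TSV.
#' @param hierarchy_path Optional path to parent-child TSV.
#' @param format \code{"auto"} (by file extension), \code{"gmt"} or
#'   \code{"tsv"}.
#' @param lenient Drop-and-log invalid hierarchy rows instead of failing.
#' @return A \code{\link{pathway_db}} object.
#' @export
read_pathways <- function(membership_path, hierarchy_path = NULL,
                          format = c("auto", "gmt", "tsv"), lenient = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", membership_path, ignore.case = TRUE))
      "gmt" else "tsv"
  }
  if (!file.exists(membership_path)) {
    stop(sprintf("input file not found: %s", membership_path), call. = FALSE)
  }
  if (format == "gmt") {
    lines <- readLines(membership_path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- vapply(fields, length, integer(1)) < 3L
    if (any(short)) {
      stop(sprintf("GMT line %d has fewer than 3 fields", which(short)[1]),
           call. = FALSE)
    }
    ids <- vapply(fields, `[[`, character(1), 1L)
    descs <- vapply(fields, `[[`, character(1), 2L)
    membership <- lapply(fields, function(f) f[-(1:2)])
    base::names(membership) <- ids
    disp <- ifelse(nzchar(descs), descs, ids)
    disp <- stats::setNames(disp, ids)
  } else {
    df <- read_tsv_checked(membership_path, c("pathway_id", "gene"))
    membership <- split(chr_trim(df$gene), chr_trim(df$pathway_id))
    disp <- NULL
    if ("name" %in% base::names(df)) {
      nm <- df$name[!duplicated(df$pathway_id)]
      disp <- stats::setNames(nm, unique(chr_trim(df$pathway_id)))
    }
  }
  hierarchy <- NULL
  if (!is.null(hierarchy_path)) {
    hdf <- read_tsv_checked(hierarchy_path, c("parent", "child"))
    hdf$parent <- chr_trim(hdf$parent)
    hdf$child <- chr_trim(hdf$child)
    unknown <- !(hdf$parent %in% base::names(membership)) |
      !(hdf$child %in% base::names(membership))
    if (any(unknown)) {
      if (!lenient) {
        stop(sprintf("%d hierarchy row(s) reference unknown pathway IDs",
                     sum(unknown)), call. = FALSE)
      }
      message(sprintf("dropping %d hierarchy row(s) referencing unknown pathway IDs",
                      sum(unknown)))
      hdf <- hdf[!unknown, , drop = FALSE]
    }
    hierarchy <- hdf
  }
  pathway_db(membership, names = disp, hierarchy = hierarchy)
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("pathway_db: %d pathways, %d universe genes, %d hierarchy edges\n",
              length(x$membership), length(x$universe), nrow(x$hierarchy)))
  invisible(x)
}

#' Read a tiered drug-target interaction table
#'
#' Expects a headered TSV with columns \code{drug}, \code{target},
#' \code{evidence_level} (I, II or III), \code{assay_type} and
#' \code{assay_value_nM}. Level III denotes interactions with at least one
#' experimental binding value, so level-III rows without an assay value are
#' invalid: dropped with a message in lenient mode, an error otherwise.
#' Assay values must be positive nanomolar quantities; empty cells mean
#' absent.
#'
#' @param path Path to the TSV.
#' @param lenient Drop-and-log invalid rows instead of failing.
#' @return A data.frame with columns \code{drug}, \code{target},
#'   \code{evidence_level}, \code{assay_type}, \code{assay_value_nM}.
#' @export
read_drug_targets <- function(path, lenient = TRUE) {
  df <- read_tsv_checked(path, c("drug", "target", "evidence_level",
                                 "assay_type", "assay_value_nM"))
  out <- data.frame(drug = chr_trim(df$drug),
                    target = chr_trim(df$target),
                    evidence_level = chr_trim(df$evidence_level),
                    assay_type = chr_trim(df$assay_type),
                    assay_value_nM = suppressWarnings(
                      as.numeric(chr_trim(df$assay_value_nM))),
                    stringsAsFactors = FALSE)
  bad_level <- !(out$evidence_level %in% c("I", "II", "III"))
  if (any(bad_level)) {
    stop(sprintf("unknown evidence level token(s): %s",
                 paste(unique(out$evidence_level[bad_level]), collapse = ", ")),
         call. = FALSE)
  }
  bad_value <- !is.na(out$assay_value_nM) & out$assay_value_nM <= 0
  no_value_iii <- out$evidence_level == "III" & is.na(out$assay_value_nM)
  bad <- bad_value | no_value_iii
  if (any(bad)) {
    if (!lenient) {
      stop(sprintf("%d invalid drug-target row(s) (non-positive or missing level-III assay values)",
                   sum(bad)), call. = FALSE)
    }
    message(sprintf("dropping %d invalid drug-target row(s)", sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  out$assay_type[out$assay_type == ""] <- NA_character_
  rownames(out) <- NULL
  out
}

#' Read a gene-symbol synonym map
#'
#' Two-column headered TSV (\code{alias<TAB>approved}). Approved symbols
#' implicitly map to themselves; an alias mapping to two different approved
#' symbols is an error.
#'
#' @param path Path to the TSV.
#' @return An object of class \code{symbol_map}: list with \code{approved}
#'   (character vector) and \code{synonym_to_approved} (named character).
#' @export
read_symbol_map <- function(path) {
  df <- read_tsv_checked(path, c("alias", "approved"))
  symbol_map(alias = chr_trim(df$alias), approved = chr_trim(df$approved))
}

#' @rdname read_symbol_map
#' @param alias Character vector of alias symbols.
#' @param approved Character vector (parallel to \code{alias}) of approved
#'   symbols.
#' @export
symbol_map <- function(alias, approved) {
  keep <- nzchar(alias) & nzchar(approved)
  alias <- alias[keep]; approved <- approved[keep]
  dup <- tapply(approved, alias, function(a) length(unique(a)))
  conflict <- names(dup)[dup > 1L]
  if (length(conflict) > 0L) {
    stop(sprintf("alias mapped to multiple approved symbols: %s",
                 paste(utils::head(conflict, 5L), collapse = ", ")),
         call. = FALSE)
  }
  approved_set <- sort(unique(approved))
  syn <- stats::setNames(approved, alias)
  syn <- syn[!duplicated(names(syn))]
  # approved symbols map to themselves, and self-mappings must not be
  # overridden by a conflicting alias row
  clash <- names(syn)[names(syn) %in% approved_set & syn != names(syn)]
  if (length(clash) > 0L) {
    stop(sprintf("approved symbol(s) remapped to a different symbol: %s",
                 paste(utils::head(clash, 5L), collapse = ", ")), call. = FALSE)
  }
  ident <- stats::setNames(approved_set, approved_set)
  syn <- c(syn[!(names(syn) %in% approved_set)], ident)
  structure(list(approved = approved_set, synonym_to_approved = syn),
            class = "symbol_map")
}

#' Normalize gene symbols through a synonym map
#'
#' Approved symbols map to themselves; aliases map through the synonym
#' table; anything else is returned as unmapped (a reported outcome, not an
#' error). Normalization is deterministic and idempotent.
#'
#' @param symbols Character vector (or set) of raw gene symbols.
#' @param map A \code{\link{symbol_map}}.
#' @return List with \code{mapped} (named character, raw -> approved) and
#'   \code{unmapped} (character vector).
#' @export
normalize_gene_symbols <- function(symbols, map) {
  stopifnot(inherits(map, "symbol_map"))
  symbols <- unique(chr_trim(symbols))
  hit <- symbols %in% names(map$synonym_to_approved)
  mapped <- stats::setNames(unname(map$synonym_to_approved[symbols[hit]]),
                            symbols[hit])
  list(mapped = mapped, unmapped = sort(symbols[!hit]))
}

# ---- writers: emit the exact formats the readers consume ----

#' Write tables in the formats the readers consume
#'
#' These writers emit MAF-like mutation tables, gene-by-sample copy-number
#' matrices, GMT membership, parent-child hierarchy TSVs and drug-target
#' TSVs, so that synthetic cohorts and pipeline reports round-trip through
#' the readers.
#'
#' @param records Data.frame of mutation (\code{patient_id}, \code{gene},
#'   \code{variant_class}) or copy-number (\code{patient_id}, \code{gene},
#'   \code{call}) records.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_maf <- function(records, path) {
  df <- data.frame(Hugo_Symbol = records$gene,
                   Tumor_Sample_Barcode = records$patient_id,
                   Variant_Classification = records$variant_class,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_maf
#' @param genes Row (gene) order of the emitted matrix; defaults to the
#'   genes present in \code{records}.
#' @param patients Column (sample) order; defaults to the patients present
#'   in \code{records}. Cells absent from \code{records} are written as 0.
#' @export
write_cna_matrix <- function(records, path, genes = NULL, patients = NULL) {
  if (is.null(genes)) genes <- sort(unique(records$gene))
  if (is.null(patients)) patients <- sort(unique(records$patient_id))
  mat <- matrix(0L, nrow = length(genes), ncol = length(patients),
                dimnames = list(genes, patients))
  keep <- records$gene %in% genes & records$patient_id %in% patients
  r <- records[keep, , drop = FALSE]
  mat[cbind(match(r$gene, genes), match(r$patient_id, patients))] <-
    as.integer(r$call)
  df <- data.frame(Gene_Symbol = genes, mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_maf
#' @param db A \code{\link{pathway_db}}.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db$membership), function(id) {
    paste(c(id, unname(db$names[id]), db$membership[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_maf
#' @export
write_hierarchy <- function(db, path) {
  write_tsv(db$hierarchy, path)
}

#' @rdname write_maf
#' @export
write_drug_targets <- function(records, path) {
  df <- records
  df$assay_value_nM <- ifelse(is.na(df$assay_value_nM), "",
                              as.character(df$assay_value_nM))
  df$assay_type[is.na(df$assay_type)] <- ""
  write_tsv(df, path)
}
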