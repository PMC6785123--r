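# Seeded synthetic-data generators with known ground truth. They emulate
# the shape of a real tumor-cohort analysis input set - a pathway database
# with a nested hierarchy, per-patient mutation / copy-number aberrations
# with planted over-aberrant pathways, a tiered drug-target table and HPV
# labels - so that every pipeline stage is testable without downloads.

#' Generate a synthetic pathway database with hierarchy
#'
#' Pathways draw their members from a shared gene pool; with
#' \code{overlap_fraction = 0} membership sets are pairwise disjoint,
#' larger values share the stated fraction of each pathway's members with
#' previously generated pathways. Each pathway is assigned a hierarchy
#' level; every pathway below the top level receives one parent from the
#' level above, so the hierarchy is acyclic by construction.
#'
#' @param n_pathways Number of pathways (default 50).
#' @param size_range Length-2 integer range of pathway sizes (default
#'   c(20, 20)).
#' @param hierarchy_depth Number of hierarchy levels (default 3).
#' @param gene_pool_size Size of the gene pool (default 1000).
#' @param overlap_fraction Fraction of each pathway's members drawn from
#'   genes already used by earlier pathways (default 0).
#' @param seed Integer seed; identical seeds give identical databases.
#' @return List with \code{db} (a \code{\link{pathway_db}}) and
#'   \code{truth} (bookkeeping: seed, sizes, universe size, levels).
#' @export
generate_pathway_db <- function(n_pathways = 50, size_range = c(20, 20),
                                hierarchy_depth = 3, gene_pool_size = 1000,
                                overlap_fraction = 0, seed = 1) {
  stopifnot(length(size_range) == 2L, size_range[1] <= size_range[2])
  if (hierarchy_depth < 1) {
    stop("hierarchy_depth must be >= 1", call. = FALSE)
  }
  if (gene_pool_size < size_range[2]) {
    stop("gene_pool_size must be at least the maximum pathway size",
         call. = FALSE)
  }
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    pool <- sprintf("G%05d", seq_len(gene_pool_size))
    unused <- sample(pool)
    used <- character(0)
    sizes <- if (size_range[1] == size_range[2]) {
      rep(size_range[1], n_pathways)
    } else {
      sample(seq(size_range[1], size_range[2]), n_pathways, replace = TRUE)
    }
    membership <- vector("list", n_pathways)
    for (i in seq_len(n_pathways)) {
      n_shared <- if (length(used) > 0L)
        min(floor(sizes[i] * overlap_fraction), length(used)) else 0L
      n_fresh <- sizes[i] - n_shared
      if (n_fresh > length(unused)) {
        stop("gene pool exhausted; increase gene_pool_size or overlap_fraction",
             call. = FALSE)
      }
      fresh <- unused[seq_len(n_fresh)]
      unused <- unused[-seq_len(n_fresh)]
      shared <- if (n_shared > 0L) sample(used, n_shared) else character(0)
      membership[[i]] <- c(fresh, shared)
      used <- c(used, fresh)
    }
    ids <- sprintf("SP%03d", seq_len(n_pathways))
    names(membership) <- ids
    level <- rep(seq_len(hierarchy_depth), length.out = n_pathways)
    hierarchy <- NULL
    if (hierarchy_depth > 1 && n_pathways > 1) {
      child_idx <- which(level > 1)
      parent <- vapply(child_idx, function(i) {
        cands <- which(level == level[i] - 1)
        ids[if (length(cands) == 1L) cands else sample(cands, 1L)]
      }, character(1))
      hierarchy <- data.frame(parent = parent, child = ids[child_idx],
                              stringsAsFactors = FALSE)
    }
    db <- pathway_db(membership,
                     names = stats::setNames(
                       sprintf("Synthetic pathway %03d", seq_len(n_pathways)),
                       ids),
                     hierarchy = hierarchy)
    list(db = db,
         truth = list(seed = seed, n_pathways = n_pathways, sizes = sizes,
                      universe_size = length(db$universe),
                      levels = stats::setNames(level, ids)))
  })
}

# Included-class sampling mix: missense-dominated, mirroring the class
# composition of typical somatic-mutation cohorts (~84% missense).
default_class_mix <- function() {
  inc <- default_impact_classes()$include
  w <- c(Missense_Mutation = 0.84, Nonsense_Mutation = 0.06,
         Frame_Shift_Del = 0.03, Frame_Shift_Ins = 0.02,
         In_Frame_Del = 0.01, In_Frame_Ins = 0.01,
         Splice_Site = 0.02, Nonstop_Mutation = 0.005,
         Translation_Start_Site = 0.005)
  w[inc]
}

#' Generate a synthetic aberration cohort with planted pathways
#'
#' Each gene in each patient is independently aberrant at
#' \code{background_rate}, overridden by the planted per-pathway member
#' rate for genes in planted pathways. Mutation mode emits MAF-like
#' records: every true aberration event carries an included
#' (high/moderate-impact) variant class drawn from \code{class_mix}, and
#' decoy records with excluded (low-impact) classes are emitted on top at
#' \code{decoy_rate} per gene-patient pair, so the impact filter is
#' exercised while the post-filter profile equals the generator's truth
#' exactly. Copy-number mode emits +/-2 calls for true aberrations (random
#' sign) and +/-1 decoy calls at \code{noise_rate}, which the +/-2
#' threshold removes.
#'
#' @param db A \code{\link{pathway_db}} (typically from
#'   \code{\link{generate_pathway_db}}).
#' @param n_patients Cohort size (default 100).
#' @param background_rate Per-gene per-patient aberration probability
#'   (default 0.02).
#' @param planted Named numeric vector, pathway ID -> member aberration
#'   rate (default none).
#' @param data_type \code{"mutation"} or \code{"copy_number"}.
#' @param seed Integer seed.
#' @param class_mix Named probability weights over included variant
#'   classes (mutation mode).
#' @param decoy_rate Rate of excluded-class decoy records (mutation mode,
#'   default 0.005).
#' @param noise_rate Rate of +/-1 decoy calls (copy-number mode, default
#'   0.02).
#' @return List with \code{records} (reader-shaped data.frame) and
#'   \code{truth} (seed, planted set, the true aberration events as a
#'   patient/gene data.frame, per-gene patient counts, cohort size,
#'   patient IDs).
#' @export
generate_cohort <- function(db, n_patients = 100, background_rate = 0.02,
                            planted = numeric(0),
                            data_type = c("mutation", "copy_number"),
                            seed = 1, class_mix = default_class_mix(),
                            decoy_rate = 0.005, noise_rate = 0.02) {
  data_type <- match.arg(data_type)
  stopifnot(inherits(db, "pathway_db"))
  rates <- c(background_rate, unname(planted), decoy_rate, noise_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  unknown <- setdiff(names(planted), names(db$membership))
  if (length(unknown) > 0L) {
    stop(sprintf("planted pathway(s) not in database: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  genes <- db$universe
  patients <- sprintf("PT%04d", seq_len(n_patients))
  rate <- stats::setNames(rep(background_rate, length(genes)), genes)
  for (pid in names(planted)) {
    rate[db$membership[[pid]]] <- planted[[pid]]
  }
  with_seed(seed, {
    # gene x patient Bernoulli draws, vectorized by column
    status <- matrix(stats::runif(length(genes) * n_patients) <
                       rep(rate, times = n_patients),
                     nrow = length(genes),
                     dimnames = list(genes, patients))
    hit <- which(status, arr.ind = TRUE)
    events <- data.frame(patient_id = patients[hit[, 2L]],
                         gene = genes[hit[, 1L]],
                         stringsAsFactors = FALSE)
    events <- events[order(events$patient_id, events$gene), , drop = FALSE]
    rownames(events) <- NULL
    if (data_type == "mutation") {
      cls <- sample(names(class_mix), nrow(events), replace = TRUE,
                    prob = class_mix)
      records <- data.frame(patient_id = events$patient_id,
                            gene = events$gene,
                            variant_class = cls, stringsAsFactors = FALSE)
      if (decoy_rate > 0) {
        decoy_hit <- which(matrix(stats::runif(length(genes) * n_patients) <
                                    decoy_rate, nrow = length(genes)),
                           arr.ind = TRUE)
        if (nrow(decoy_hit) > 0L) {
          excl <- default_impact_classes()$exclude
          decoys <- data.frame(
            patient_id = patients[decoy_hit[, 2L]],
            gene = genes[decoy_hit[, 1L]],
            variant_class = sample(excl, nrow(decoy_hit), replace = TRUE),
            stringsAsFactors = FALSE)
          records <- rbind(records, decoys)
        }
      }
      records <- records[order(records$patient_id, records$gene,
                               records$variant_class), , drop = FALSE]
    } else {
      call_val <- sample(c(-2L, 2L), nrow(events), replace = TRUE)
      records <- data.frame(patient_id = events$patient_id,
                            gene = events$gene,
                            call = call_val, stringsAsFactors = FALSE)
      if (noise_rate > 0) {
        noise_hit <- which(matrix(stats::runif(length(genes) * n_patients) <
                                    noise_rate, nrow = length(genes)) &
                             !status, arr.ind = TRUE)
        if (nrow(noise_hit) > 0L) {
          noise <- data.frame(
            patient_id = patients[noise_hit[, 2L]],
            gene = genes[noise_hit[, 1L]],
            call = sample(c(-1L, 1L), nrow(noise_hit), replace = TRUE),
            stringsAsFactors = FALSE)
          records <- rbind(records, noise)
        }
      }
      records <- records[order(records$patient_id, records$gene), ,
                         drop = FALSE]
    }
    rownames(records) <- NULL
    gene_patient_counts <- table(events$gene)
    list(records = records,
         truth = list(seed = seed, data_type = data_type,
                      planted = planted,
                      background_rate = background_rate,
                      n_patients = n_patients,
                      patients = patients,
                      events = events,
                      n_events = nrow(events),
                      gene_patient_counts =
                        stats::setNames(as.integer(gene_patient_counts),
                                        names(gene_patient_counts)),
                      cohort_size = length(unique(events$patient_id))))
  })
}

#' Generate a synthetic tiered drug-target table
#'
#' A fraction of pathways receive one to three targeted member genes; each
#' target is hit by one to three drugs from a small drug pool, each
#' drug-target interaction carrying an evidence level drawn from
#' \code{level_mix} (level III records get a binding value sampled
#' log-uniformly within \code{binding_value_range_nM}, with assay type KD
#' or IC50; level I/II records carry none). The truth records which
#' pathways contain at least one targeted gene and therefore must classify
#' light if enriched.
#'
#' @param db A \code{\link{pathway_db}}.
#' @param fraction_pathways_targeted Fraction of pathways seeded with a
#'   target (default 0.5).
#' @param level_mix Named probabilities for levels I, II, III (default
#'   c(I = 0.01, II = 0.15, III = 0.84)).
#' @param binding_value_range_nM Length-2 positive range for level-III
#'   assay values (default c(0.1, 10000)).
#' @param n_drugs Size of the drug name pool (default 20).
#' @param seed Integer seed.
#' @return List with \code{records} (drug-target data.frame) and
#'   \code{truth} (seed, seeded pathways, target genes, and
#'   \code{targeted_pathways}: all pathways containing >= 1 targeted
#'   gene).
#' @export
generate_targetome <- function(db, fraction_pathways_targeted = 0.5,
                               level_mix = c(I = 0.01, II = 0.15, III = 0.84),
                               binding_value_range_nM = c(0.1, 10000),
                               n_drugs = 20, seed = 1) {
  stopifnot(inherits(db, "pathway_db"))
  if (fraction_pathways_targeted < 0 || fraction_pathways_targeted > 1) {
    stop("fraction_pathways_targeted must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(all(c("I", "II", "III") %in% names(level_mix)),
            all(binding_value_range_nM > 0),
            length(binding_value_range_nM) == 2L)
  ids <- names(db$membership)
  n_seeded <- round(fraction_pathways_targeted * length(ids))
  with_seed(seed, {
    seeded <- if (n_seeded > 0L) sort(sample(ids, n_seeded)) else character(0)
    drug_pool <- sprintf("DRUG%03d", seq_len(n_drugs))
    target_genes <- character(0)
    for (pid in seeded) {
      members <- db$membership[[pid]]
      n_t <- min(length(members), sample(1:3, 1L))
      target_genes <- c(target_genes, sample(members, n_t))
    }
    target_genes <- sort(unique(target_genes))
    rows <- list()
    for (tg in target_genes) {
      drugs <- sample(drug_pool, sample(1:3, 1L))
      for (d in drugs) {
        lv <- sample(c("I", "II", "III"), 1L, prob = level_mix[c("I", "II", "III")])
        if (lv == "III") {
          lo <- log(binding_value_range_nM[1]); hi <- log(binding_value_range_nM[2])
          val <- exp(stats::runif(1L, lo, hi))
          at <- sample(c("KD", "IC50"), 1L)
        } else {
          val <- NA_real_; at <- NA_character_
        }
        rows[[length(rows) + 1L]] <- data.frame(
          drug = d, target = tg, evidence_level = lv,
          assay_type = at, assay_value_nM = val, stringsAsFactors = FALSE)
      }
    }
    records <- if (length(rows) > 0L) do.call(rbind, rows) else
      data.frame(drug = character(0), target = character(0),
                 evidence_level = character(0), assay_type = character(0),
                 assay_value_nM = numeric(0), stringsAsFactors = FALSE)
    rownames(records) <- NULL
    targeted <- ids[vapply(db$membership,
                           function(g) any(g %in% target_genes), logical(1))]
    list(records = records,
         truth = list(seed = seed, seeded_pathways = seeded,
                      target_genes = target_genes,
                      targeted_pathways = sort(targeted)))
  })
}

#' Generate a synthetic clinical table with HPV annotation sources
#'
#' Assigns the first \code{n_positive} patients source calls that tier as
#' HPV-positive at highest confidence (primary source positive with WGS
#' available), the next \code{n_negative} patients calls that tier as
#' high-confidence negative, and leaves the rest unclassified (unknown
#' primary call, no WGS). Anatomic sites are sampled from the raw
#' vocabulary the site collapser understands, plus an occasional
#' unrecognized label. Patient order is shuffled under the seed.
#'
#' @param patient_ids Character vector of cohort patient IDs.
#' @param n_positive,n_negative Stratum sizes (defaults 57 and 118).
#' @param seed Integer seed.
#' @return Data.frame with columns \code{patient_id}, \code{nulton_call},
#'   \code{wgs_available}, \code{tcga_clinical_call},
#'   \code{tcga_nature_call}, \code{anatomic_site}.
#' @export
generate_clinical <- function(patient_ids, n_positive = 57, n_negative = 118,
                              seed = 1) {
  n <- length(patient_ids)
  if (n_positive + n_negative > n) {
    stop("n_positive + n_negative exceeds the number of patients",
         call. = FALSE)
  }
  with_seed(seed, {
    shuffled <- sample(patient_ids)
    status <- rep("unclassified", n)
    status[seq_len(n_positive)] <- "positive"
    status[n_positive + seq_len(n_negative)] <- "negative"
    nulton <- ifelse(status == "positive", "positive",
                     ifelse(status == "negative", "negative", "unknown"))
    wgs <- status != "unclassified"
    corroborate <- status == "positive" & stats::runif(n) < 0.5
    sites <- c("Alveolar Ridge", "Buccal Mucosa", "Floor of mouth",
               "Hard Palate", "Hypopharynx", "Lip", "Oral Cavity",
               "Oral Tongue", "Base of tongue", "Tonsil", "Larynx",
               "Parotid Gland")
    df <- data.frame(
      patient_id = shuffled,
      nulton_call = nulton,
      wgs_available = wgs,
      tcga_clinical_call = ifelse(corroborate, "positive", "unknown"),
      tcga_nature_call = "unknown",
      anatomic_site = sample(sites, n, replace = TRUE),
      stringsAsFactors = FALSE)
    df[order(df$patient_id), , drop = FALSE]
  })
}
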