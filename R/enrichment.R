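#' Upper-tail hypergeometric p-value for pathway over-representation
#'
#' With a gene universe of size \code{N} (all genes belonging to at least
#' one pathway), a pathway of \code{m} member genes, \code{K} aberrant
#' genes in the universe and \code{k} aberrant pathway members, the test
#' asks how surprising an overlap of \code{k} is when \code{m} genes are
#' drawn from the universe without replacement. Two tail conventions are
#' supported:
#' \itemize{
#'   \item \code{"ge"} (default): the inclusive tail P(X >= k), the
#'     standard over-representation convention;
#'   \item \code{"gt"}: the exclusive tail P(X > k), i.e. one minus the
#'     inclusive CDF at \code{k}. Under this convention a fully covered
#'     pathway (\code{k = m}) has p exactly 0, which gives the test power
#'     in cohorts where most universe genes carry at least one aberration,
#'     at the cost of anti-conservative behaviour (see the methods
#'     vignette).
#' }
#' The test is symmetric in \code{m} and \code{K}.
#'
#' @param N Universe size (genes in >= 1 pathway).
#' @param m Pathway gene count.
#' @param K Aberrant genes in the universe.
#' @param k Aberrant genes in the pathway.
#' @param tail \code{"ge"} or \code{"gt"}.
#' @return Numeric vector of p-values in [0, 1]; arguments recycle.
#' @export
hypergeom_pvalue <- function(N, m, K, k, tail = c("ge", "gt")) {
  tail <- match.arg(tail)
  n_args <- max(length(N), length(m), length(K), length(k))
  N <- rep_len(as.numeric(N), n_args); m <- rep_len(as.numeric(m), n_args)
  K <- rep_len(as.numeric(K), n_args); k <- rep_len(as.numeric(k), n_args)
  if (any(N < 0 | m < 0 | K < 0 | k < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(m > N) || any(K > N)) {
    stop("pathway size m and aberrant count K cannot exceed universe size N",
         call. = FALSE)
  }
  if (any(k > pmin(m, K))) {
    stop("overlap k cannot exceed min(m, K)", call. = FALSE)
  }
  q <- if (tail == "ge") k - 1 else k
  stats::phyper(q, m = K, n = N - K, k = m, lower.tail = FALSE)
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Adjusts p-values for multiple testing under arbitrary dependence:
#' q_(i) = min over j >= i of min(1, p_(j) * n/j * c(n)) with
#' c(n) = sum_(t=1..n) 1/t, returned in the input order.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @export
adjust_by <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BY")
}

#' Pathway over-representation analysis for an aberration profile
#'
#' Tests every pathway in the database for over-representation of the
#' cohort's aberrant genes (genes aberrant in at least one patient),
#' adjusts jointly with Benjamini-Yekutieli over the full pathway count
#' (pathways with zero overlap are still tested at p = 1 so the
#' multiplicity is reproducible), and flags pathways with q below
#' \code{alpha} as enriched.
#'
#' Aberrant genes outside the universe do not contribute to \code{K}: the
#' population of the test is the set of genes belonging to at least one
#' pathway.
#'
#' @param profile An \code{\link{build_aberration_profile}} result.
#' @param db A \code{\link{pathway_db}}.
#' @param alpha FDR threshold (default 0.05).
#' @param tail Tail convention passed to \code{\link{hypergeom_pvalue}}.
#' @return Data.frame with one row per pathway: \code{pathway_id},
#'   \code{name}, \code{N}, \code{m}, \code{K}, \code{k}, \code{p_value},
#'   \code{q_value}, \code{enriched}.
#' @export
enrich_pathways <- function(profile, db, alpha = 0.05, tail = c("ge", "gt")) {
  stopifnot(inherits(profile, "aberration_profile"), inherits(db, "pathway_db"))
  tail <- match.arg(tail)
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha >= 0 && alpha < 1)) {
    stop("alpha must be a single value in [0, 1)", call. = FALSE)
  }
  aberrant <- names(profile$gene_patients)
  universe <- db$universe
  N <- length(universe)
  hits <- intersect(aberrant, universe)
  K <- length(hits)
  ids <- names(db$membership)
  m <- vapply(db$membership, length, integer(1))
  k <- vapply(db$membership, function(g) sum(g %in% hits), integer(1))
  if (K == 0L) {
    warning("no aberrant genes fall in the pathway universe; all p-values set to 1",
            call. = FALSE)
    p <- rep(1, length(ids))
  } else {
    p <- hypergeom_pvalue(N, m, K, k, tail = tail)
  }
  q <- adjust_by(p)
  data.frame(pathway_id = ids,
             name = unname(db$names[ids]),
             N = N, m = unname(m), K = K, k = unname(k),
             p_value = unname(p), q_value = unname(q),
             enriched = unname(q < alpha),
             stringsAsFactors = FALSE, row.names = NULL)
}
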