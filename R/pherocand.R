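#' Log-transformed intensity (LTI) per gene within one group
#'
#' The LTI of a gene in a group is the mean of its log-scale expression
#' values over that group's biological replicates; technical replicates
#' are excluded.
#'
#' @param x a log-scale [contig_expression()].
#' @param group group name.
#' @param gene_set character vector of contig/gene ids (>= 1).
#' @return Named numeric vector of LTIs.
#' @export
compute_lti <- function(x, group, gene_set) {
  stopifnot(inherits(x, "contig_expression"))
  if (x$scale != "log") stop("compute_lti expects the log-scale table")
  if (length(gene_set) == 0L) stop("gene set is empty")
  miss <- setdiff(gene_set, rownames(x$values))
  if (length(miss)) stop("gene(s) absent from the table: ",
                         paste(miss, collapse = ", "))
  sel <- x$samples$group == group & x$samples$replicate_type == "biological"
  if (!any(sel)) stop("no biological replicates for group '", group, "'")
  rowMeans(x$values[gene_set, sel, drop = FALSE])
}

#' Expression-factor context for a gene set within a group
#'
#' Fixes the reference distribution of the expression factor: the LTI
#' vector over the whole gene set (e.g. all OR genes and OR gene
#' fragments) in one group, its mean, and its standard deviation
#' (sample sd, n - 1 denominator).
#'
#' @param x a log-scale [contig_expression()].
#' @param group group in which expression is assessed.
#' @param gene_set ids of the gene set (>= 2 members).
#' @return list of class `ef_context` with `lti`, `lti_mean`, `sd`,
#'   `group`, `gene_set`.
#' @export
ef_context <- function(x, group, gene_set) {
  if (length(gene_set) < 2L) stop("gene set needs at least 2 members")
  lti <- compute_lti(x, group, gene_set)
  sdv <- stats::sd(lti)
  if (!is.finite(sdv) || sdv == 0)
    stop("degenerate gene set: zero LTI standard deviation in group '",
         group, "'")
  structure(list(lti = lti, lti_mean = mean(lti), sd = sdv,
                 group = group, gene_set = gene_set),
            class = "ef_context")
}

#' Expression factor (EF)
#'
#' The z-score of a gene's log-transformed intensity within the LTI
#' distribution of its gene set: `EF = (LTI_cand - LTI_mean) / SD`. Over
#' the whole gene set the EF vector has mean 0 and standard deviation 1.
#'
#' @param context an [ef_context()].
#' @param gene a single gene id, or NULL for the whole set.
#' @return Named numeric vector of EF values.
#' @export
expression_factor <- function(context, gene = NULL) {
  stopifnot(inherits(context, "ef_context"))
  if (is.null(gene)) return((context$lti - context$lti_mean) / context$sd)
  if (!gene %in% names(context$lti))
    stop("gene '", gene, "' is not in the gene set")
  (context$lti[[gene]] - context$lti_mean) / context$sd
}

#' Between-group log-fold difference of LTIs
#'
#' `LTI(group_a) - LTI(group_b)` per gene; antisymmetric under swapping
#' the groups. On a base-2 log scale this is the log2 fold-change.
#'
#' @param x a log-scale [contig_expression()].
#' @param group_a,group_b the two groups.
#' @param genes gene ids (default: all contigs in the table).
#' @return Named numeric vector of log-scale differences.
#' @export
log_fold <- function(x, group_a, group_b, genes = NULL) {
  if (is.null(genes)) genes <- rownames(x$values)
  compute_lti(x, group_a, genes) - compute_lti(x, group_b, genes)
}

#' Screen a gene set for candidate pheromone receptors
#'
#' Combines overall high expression with differential expression in a
#' biologically relevant range: within the focal group `group_a`, the EF
#' of every gene in the set is computed, together with the log-fold
#' difference versus `group_b`. Candidates are genes with
#' `EF >= ef_min` and `log_fold >= band_halfwidth` (log-fold differences
#' inside the +/- band are treated as biologically irrelevant; candidacy
#' requires enrichment in the focal group). The returned table contains
#' every gene, ranked by EF descending with ties broken by log-fold
#' descending and then by gene id.
#'
#' @param x a log-scale [contig_expression()].
#' @param group_a focal group (where high expression is sought).
#' @param group_b comparison group.
#' @param gene_set ids of the gene set (>= 2).
#' @param ef_min minimum EF for candidacy (default 2).
#' @param band_halfwidth half-width of the irrelevance band on the
#'   log-fold axis (default 0.5).
#' @return data.frame of class `ef_screen`: `gene_id`, `lti_cand`, `ef`,
#'   `log_fold`, `fold_linear`, `candidate`, sorted as described.
#' @export
candidate_screen <- function(x, group_a, group_b, gene_set,
                             ef_min = 2, band_halfwidth = 0.5) {
  if (ef_min < 0 || band_halfwidth < 0)
    stop("ef_min and band_halfwidth must be nonnegative")
  ctx <- ef_context(x, group_a, gene_set)
  ef <- expression_factor(ctx)
  lf <- log_fold(x, group_a, group_b, gene_set)
  base <- if (is.finite(x$log_base)) x$log_base else 2
  out <- data.frame(gene_id = names(ef), lti_cand = unname(ctx$lti),
                    ef = unname(ef), log_fold = unname(lf),
                    fold_linear = base^unname(lf),
                    candidate = unname(ef >= ef_min & lf >= band_halfwidth),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ef, -out$log_fold, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "group_a") <- group_a
  attr(out, "group_b") <- group_b
  attr(out, "ef_min") <- ef_min
  attr(out, "band_halfwidth") <- band_halfwidth
  class(out) <- c("ef_screen", "data.frame")
  out
}

#' @export
print.ef_screen <- function(x, n = 5L, ...) {
  cat("ef_screen: ", nrow(x), " genes, ", attr(x, "group_a"), " vs ",
      attr(x, "group_b"), "; ", sum(x$candidate), " candidate(s) (EF >= ",
      attr(x, "ef_min"), ", log-fold >= ", attr(x, "band_halfwidth"),
      ")\n", sep = "")
  top <- utils::head(as.data.frame(x), n)
  print(top, digits = 3)
  invisible(x)
}

#' Candidate rows of an EF screen
#' @param x an `ef_screen`.
#' @return data.frame of the flagged candidates, in rank order.
#' @export
candidates <- function(x) {
  stopifnot(inherits(x, "ef_screen"))
  as.data.frame(x)[x$candidate, , drop = FALSE]
}

#' Percentile rank of a gene's LTI within a reference set
#'
#' The percentage of reference genes whose LTI in the stated group lies
#' strictly below the gene's LTI; ties count one half (midrank). The gene
#' itself is excluded from the reference set when present, so a gene above
#' every other reference gene ranks 100.
#'
#' @param x a log-scale [contig_expression()].
#' @param group group name.
#' @param gene a single gene id.
#' @param reference_set ids of the reference genes.
#' @return Percent in \[0, 100\].
#' @export
percentile_rank <- function(x, group, gene, reference_set) {
  stopifnot(length(gene) == 1L)
  ref <- setdiff(reference_set, gene)
  if (length(ref) == 0L) stop("reference set is empty")
  lti <- compute_lti(x, group, c(gene, ref))
  g <- lti[[gene]]
  r <- lti[ref]
  100 * (sum(r < g) + 0.5 * sum(r == g)) / length(r)
}
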