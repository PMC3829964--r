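#' GO-term frequencies within a category and level
#'
#' Counts the number of distinct contigs carrying each term, restricted to
#' a GO category (molecular function, biological process, cellular
#' component) and annotation level. A contig contributes to every term it
#' carries; duplicate (contig, term) rows collapse to one.
#'
#' @param annotations data.frame with columns `contig_id`, `term`,
#'   `category`, `level`.
#' @param category optional category filter; must occur in the table.
#' @param level optional level filter.
#' @return data.frame with columns `term`, `n_contigs`, sorted by count
#'   descending then term.
#' @export
term_frequencies <- function(annotations, category = NULL, level = NULL) {
  a <- .check_annotations(annotations)
  if (!is.null(category)) {
    if (!category %in% a$category)
      stop("category '", category, "' not present in the annotation table")
    a <- a[a$category == category, , drop = FALSE]
  }
  if (!is.null(level)) a <- a[a$level == level, , drop = FALSE]
  a <- unique(a[, c("contig_id", "term")])
  if (nrow(a) == 0L)
    return(data.frame(term = character(), n_contigs = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(a$term)
  out <- data.frame(term = names(tab), n_contigs = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_contigs, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.check_annotations <- function(annotations) {
  a <- as.data.frame(annotations, stringsAsFactors = FALSE)
  req <- c("contig_id", "term", "category", "level")
  if (!all(req %in% names(a)))
    stop("annotation table must have columns ", paste(req, collapse = ", "))
  ncat <- tapply(a$category, a$term, function(z) length(unique(z)))
  if (any(ncat > 1L))
    stop("term(s) with more than one category: ",
         paste(names(ncat)[ncat > 1L], collapse = ", "))
  a
}

#' Group-level presence from per-sample calls
#'
#' A contig is called present in a group when it is present on at least
#' `min_frac` of that group's arrays (majority rule by default; technical
#' replicates count as arrays).
#'
#' @param presence logical matrix from [presence_calls()].
#' @param samples the sample sheet matching the columns of `presence`.
#' @param min_frac minimum fraction of present arrays (default 0.5).
#' @return Logical matrix, contigs x groups.
#' @export
group_presence <- function(presence, samples, min_frac = 0.5) {
  if (ncol(presence) != nrow(samples))
    stop("sample sheet does not match the presence matrix")
  g <- factor(samples$group)
  frac <- t(rowsum(t(presence * 1), g) / as.vector(table(g)))
  out <- frac >= min_frac
  colnames(out) <- levels(g)
  out
}

#' Chi-square comparison of one GO term's presence across groups
#'
#' Builds the 2 x k contingency table of contigs that are present in each
#' group and annotated with the term versus present but not annotated, and
#' applies Pearson's chi-square test without continuity correction.
#' Expected counts below 5 are flagged, not corrected. Groups with zero
#' present contigs cause the test to be skipped with a flag.
#'
#' @param term the term id.
#' @param group_present logical contigs x groups matrix from
#'   [group_presence()].
#' @param annotations annotation table (see [term_frequencies()]).
#' @return list of class `term_comparison`: `term`, `counts` (2 x k
#'   matrix, rows annotated/not), `statistic`, `df`, `p.value`,
#'   `low_expected`, `skipped`.
#' @export
per_term_chisq <- function(term, group_present, annotations) {
  a <- .check_annotations(annotations)
  if (ncol(group_present) < 2L) stop("need at least 2 groups")
  annotated_ids <- unique(a$contig_id[a$term == term])
  ann <- rownames(group_present) %in% annotated_ids
  counts <- rbind(annotated = colSums(group_present & ann),
                  not_annotated = colSums(group_present & !ann))
  empty <- colSums(counts) == 0L
  if (any(empty)) {
    return(structure(list(term = term, counts = counts,
                          statistic = NA_real_, df = NA_integer_,
                          p.value = NA_real_, low_expected = NA,
                          skipped = TRUE), class = "term_comparison"))
  }
  if (all(counts["annotated", ] == 0L) || all(counts["not_annotated", ] == 0L)) {
    # term absent (or universal) among present contigs: no contrast to test
    stat <- 0
    df <- ncol(counts) - 1L
    p <- 1
    low <- TRUE
  } else {
    ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    stat <- unname(ct$statistic)
    df <- unname(ct$parameter)
    p <- unname(ct$p.value)
    low <- any(ct$expected < 5)
  }
  structure(list(term = term, counts = counts, statistic = stat,
                 df = df, p.value = p, low_expected = low,
                 skipped = FALSE),
            class = "term_comparison")
}

#' @export
print.term_comparison <- function(x, ...) {
  cat("term ", x$term, ": ", sep = "")
  if (x$skipped) {
    cat("skipped (a group has no present contigs)\n")
  } else {
    cat("chi-square = ", format(x$statistic, digits = 4), ", df = ", x$df,
        ", p = ", format(x$p.value, digits = 4),
        if (isTRUE(x$low_expected)) " [expected count < 5]", "\n", sep = "")
  }
  print(x$counts)
  invisible(x)
}

#' Per-term chi-square screen over all GO terms
#'
#' Tests every term independently (no correction across terms, matching
#' per-term reporting) and returns the results sorted by p ascending.
#'
#' @param annotations annotation table.
#' @param presence per-sample logical matrix from [presence_calls()].
#' @param samples sample sheet matching `presence`.
#' @param alpha significance level for the summary flag.
#' @param category,level optional filters applied to the annotation table
#'   before testing.
#' @param min_frac group-presence majority fraction (see
#'   [group_presence()]).
#' @return data.frame of class `go_screen`: `term`, one `present_<group>`
#'   count column per group (annotated contigs present in the group),
#'   `statistic`, `df`, `p`, `low_expected`, `skipped`; attribute
#'   `any_significant`.
#' @export
screen_all_terms <- function(annotations, presence, samples, alpha = 0.05,
                             category = NULL, level = NULL,
                             min_frac = 0.5) {
  a <- .check_annotations(annotations)
  if (!is.null(category)) a <- a[a$category == category, , drop = FALSE]
  if (!is.null(level)) a <- a[a$level == level, , drop = FALSE]
  if (length(unique(samples$group)) < 2L) stop("need at least 2 groups")
  gp <- group_presence(presence, samples, min_frac = min_frac)
  terms <- sort(unique(a$term))
  res <- lapply(terms, per_term_chisq, group_present = gp, annotations = a)
  k <- ncol(gp)
  cnt <- t(vapply(res, function(r) r$counts["annotated", ], numeric(k)))
  out <- data.frame(term = terms, cnt,
                    statistic = vapply(res, `[[`, numeric(1), "statistic"),
                    df = vapply(res, function(r) as.numeric(r$df), numeric(1)),
                    p = vapply(res, `[[`, numeric(1), "p.value"),
                    low_expected = vapply(res, function(r)
                      isTRUE(r$low_expected), logical(1)),
                    skipped = vapply(res, `[[`, logical(1), "skipped"),
                    stringsAsFactors = FALSE)
  names(out)[1L + seq_len(k)] <- paste0("present_", colnames(gp))
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "groups") <- colnames(gp)
  attr(out, "alpha") <- alpha
  attr(out, "any_significant") <- any(out$p <= alpha, na.rm = TRUE)
  class(out) <- c("go_screen", "data.frame")
  out
}

#' @export
print.go_screen <- function(x, n = 5L, ...) {
  cat("go_screen: ", nrow(x), " terms across groups ",
      paste(attr(x, "groups"), collapse = "/"), "\n", sep = "")
  sig <- sum(x$p <= attr(x, "alpha"), na.rm = TRUE)
  cat(if (attr(x, "any_significant"))
    paste0(sig, " term(s) with p <= ", attr(x, "alpha"), "\n")
    else paste0("no term differs at alpha = ", attr(x, "alpha"),
                " (all p-values > ", attr(x, "alpha"), ")\n"))
  print(utils::head(as.data.frame(x), n), digits = 4)
  invisible(x)
}

#' Compute GO levels from an ontology edge list
#'
#' Optional helper when the input annotations lack levels: the level of a
#' term is 1 + the shortest-path distance (in parent edges) from its
#' category root, with roots at level 1.
#'
#' @param edges data.frame with columns `term_id`, `parent_id`.
#' @return Named integer vector of levels; terms unreachable from a root
#'   get NA.
#' @export
go_levels_from_edges <- function(edges) {
  e <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("term_id", "parent_id") %in% names(e)))
    stop("edge list must have columns term_id, parent_id")
  terms <- unique(c(e$term_id, e$parent_id))
  lev <- stats::setNames(rep(NA_integer_, length(terms)), terms)
  roots <- setdiff(e$parent_id, e$term_id)
  lev[roots] <- 1L
  frontier <- roots
  d <- 1L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(e$term_id[e$parent_id %in% frontier])
    nxt <- nxt[is.na(lev[nxt])]
    lev[nxt] <- d
    frontier <- nxt
  }
  lev
}
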