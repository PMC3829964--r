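# Row-wise one-way fixed-effects ANOVA. x: matrix (rows = contigs),
# g: factor of column groups. Returns F, p, the within-group mean square
# and error df (needed downstream by the SNK step).
.row_anova <- function(x, g) {
  g <- factor(g)
  k <- nlevels(g)
  n <- tabulate(g)
  if (k < 2L) stop("need at least 2 groups")
  if (any(n < 2L))
    stop("every group needs at least 2 observations (got ",
         paste(n, collapse = "/"), ")")
  N <- sum(n)
  gm <- t(rowsum(t(x), g) / n)                 # rows x k group means
  grand <- as.vector(x %*% rep(1 / N, N))
  ssb <- as.vector((gm - grand)^2 %*% n)
  sst <- rowSums((x - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  msb <- ssb / (k - 1)
  mse <- ssw / (N - k)
  f <- msb / mse
  p <- stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  # degenerate rows: all values identical -> no variance to test
  flat <- sst <= 0
  f[flat] <- 0
  p[flat] <- 1
  sep <- !flat & ssw <= 0                       # perfect separation
  f[sep] <- Inf
  p[sep] <- 0
  list(statistic = f, p.value = p, mse = mse, df_error = N - k,
       group_means = gm, n = n)
}

# Row-wise classical (pooled-variance) two-sided t-test.
.row_ttest <- function(x, g) {
  g <- factor(g)
  if (nlevels(g) != 2L) stop("t-test needs exactly 2 groups")
  n <- tabulate(g)
  if (any(n < 2L)) stop("every group needs at least 2 observations")
  i1 <- g == levels(g)[1L]
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, !i1, drop = FALSE])
  v1 <- rowSums((x[, i1, drop = FALSE] - m1)^2) / (n[1] - 1)
  v2 <- rowSums((x[, !i1, drop = FALSE] - m2)^2) / (n[2] - 1)
  df <- n[1] + n[2] - 2
  sp2 <- ((n[1] - 1) * v1 + (n[2] - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n[1] + 1 / n[2]))
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  same <- se <= 0 & m1 == m2
  t[same] <- 0
  p[same] <- 1
  degen <- se <= 0 & m1 != m2                   # zero pooled variance
  t[degen] <- sign(m1 - m2)[degen] * Inf
  p[degen] <- 0
  list(statistic = t, p.value = p, df = df, degenerate = degen,
       mse = sp2, n = n)
}

#' One-way fixed-effects ANOVA for a single contig
#'
#' Standard F-test with (k-1, N-k) degrees of freedom. If all values are
#' identical (zero total sum of squares) the test is vacuous and returns
#' F = 0, p = 1.
#'
#' @param x numeric vector of observations.
#' @param g grouping factor/vector of the same length, with k >= 2 levels
#'   and at least 2 observations per group.
#' @return list with `statistic` (F), `df` = c(k-1, N-k), `p.value`, and
#'   the within-group mean square `mse`.
#' @export
one_way_anova <- function(x, g) {
  g <- factor(g)
  r <- .row_anova(matrix(as.numeric(x), nrow = 1L), g)
  list(statistic = r$statistic[1L],
       df = c(nlevels(g) - 1L, r$df_error),
       p.value = r$p.value[1L], mse = r$mse[1L])
}

#' Classical two-sample t-test (pooled variance, two-sided, unpaired)
#'
#' @param x,y numeric vectors of the two groups, each of length >= 2.
#' @return list with `statistic` (t), `df`, `p.value`, and `degenerate`
#'   (TRUE when the pooled variance is zero with unequal means, reported
#'   as p = 0).
#' @export
two_group_ttest <- function(x, y) {
  m <- matrix(as.numeric(c(x, y)), nrow = 1L)
  g <- factor(rep(c("a", "b"), c(length(x), length(y))), levels = c("a", "b"))
  r <- .row_ttest(m, g)
  list(statistic = r$statistic[1L], df = r$df, p.value = r$p.value[1L],
       degenerate = r$degenerate[1L])
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values under the BH false-discovery-rate procedure:
#' `adj_(i) = min_{j >= i} (m * p_(j) / j)` over the sorted p-values,
#' capped at 1 and mapped back to the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Filter thresholds of the differential-expression cascade
#'
#' @param min_mean_intensity contigs whose maximum linear group mean falls
#'   below this are excluded as not expressed (default 100).
#' @param min_fold minimum max/min group-mean ratio for a difference to
#'   count as biologically relevant (default 2).
#' @param alpha significance level on the BH-adjusted p-value.
#' @return list of class `de_thresholds`.
#' @export
de_thresholds <- function(min_mean_intensity = 100, min_fold = 2,
                          alpha = 0.05) {
  if (min_fold < 1) stop("min_fold must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(min_mean_intensity = min_mean_intensity,
                 min_fold = min_fold, alpha = alpha),
            class = "de_thresholds")
}

#' Differential expression table for one dataset
#'
#' Runs the full cascade on a linear-scale contig table: linear group
#' means; the expression gate (max group mean >= `min_mean_intensity`);
#' a one-way ANOVA (3+ groups) or pooled t-test (2 groups) on log-scale
#' values; Benjamini-Hochberg adjustment across all expressed contigs;
#' the Student-Newman-Keuls post-hoc grouping for ANOVA-significant
#' contigs; and the fold gate (max pairwise ratio of linear group means
#' >= `min_fold`). A contig is `relevant` when it is expressed,
#' significant after adjustment, and passes the fold gate. Technical
#' replicates count as ordinary observations of their group.
#'
#' @param x a linear-scale [contig_expression()].
#' @param dataset optional dataset id to select before testing; the
#'   selected samples must form a single dataset.
#' @param thresholds a [de_thresholds()].
#' @param log_base,log_offset parameters of the log transform used for
#'   testing (and for [heatmap_matrix()] display values).
#' @return A data.frame of class `de_table`: `contig_id`, one
#'   `mean_<group>` column per group (linear scale), `max_ratio`,
#'   `statistic`, `p`, `p_adj`, `snk` (letter grouping, `""` when not
#'   computed), `expressed`, `relevant`. Non-expressed contigs carry NA
#'   test results.
#' @export
de_table <- function(x, dataset = NULL, thresholds = de_thresholds(),
                     log_base = 2, log_offset = 1) {
  stopifnot(inherits(x, "contig_expression"))
  if (x$scale != "linear")
    stop("de_table expects the linear-scale table; it logs internally")
  if (!is.null(dataset)) {
    sel <- x$samples$dataset == dataset
    if (!any(sel)) stop("no samples in dataset ", dataset)
    x <- subset_samples(x, which(sel))
  }
  if (length(unique(x$samples$dataset)) > 1L)
    stop("samples from mixed datasets; pass a dataset id")
  g <- factor(x$samples$group)
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups")
  n <- tabulate(g)
  lin_means <- t(rowsum(t(x$values), g) / n)    # contigs x groups, linear
  colnames(lin_means) <- levels(g)
  expressed <- apply(lin_means, 1L, max) >= thresholds$min_mean_intensity
  max_ratio <- apply(lin_means, 1L, max) / apply(lin_means, 1L, min)

  logv <- log(x$values + log_offset, log_base)
  nc <- nrow(x$values)
  p <- p_adj <- stat <- rep(NA_real_, nc)
  snk <- rep("", nc)
  if (any(expressed)) {
    sub <- logv[expressed, , drop = FALSE]
    if (k == 2L) {
      r <- .row_ttest(sub, g)
    } else {
      r <- .row_anova(sub, g)
    }
    stat[expressed] <- r$statistic
    p[expressed] <- r$p.value
    p_adj[expressed] <- bh_adjust(r$p.value)
    if (k >= 3L) {
      sig <- which(expressed)[p_adj[expressed] <= thresholds$alpha]
      for (i in sig) {
        ri <- match(i, which(expressed))
        grp <- snk_posthoc(r$group_means[ri, ], n = r$n,
                           mse = max(r$mse[ri], .Machine$double.xmin),
                           df_error = r$df_error,
                           alpha = thresholds$alpha)
        snk[i] <- paste(grp$letters, collapse = "/")
      }
    }
  }
  relevant <- expressed & !is.na(p_adj) & p_adj <= thresholds$alpha &
    max_ratio >= thresholds$min_fold
  out <- data.frame(contig_id = rownames(x$values),
                    lin_means,
                    max_ratio = max_ratio, statistic = stat,
                    p = p, p_adj = p_adj, snk = snk,
                    expressed = expressed, relevant = relevant,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[1L + seq_len(k)] <- paste0("mean_", levels(g))
  attr(out, "groups") <- levels(g)
  attr(out, "test") <- if (k == 2L) "ttest" else "anova"
  attr(out, "thresholds") <- thresholds
  attr(out, "log_base") <- log_base
  attr(out, "log_offset") <- log_offset
  class(out) <- c("de_table", "data.frame")
  out
}

#' @export
print.de_table <- function(x, ...) {
  thr <- attr(x, "thresholds")
  cat("de_table (", attr(x, "test"), "): ", nrow(x), " contigs, groups ",
      paste(attr(x, "groups"), collapse = "/"), "\n", sep = "")
  cat(sum(x$expressed), " expressed (mean >= ", thr$min_mean_intensity,
      "), ", sum(x$relevant), " relevant (p_adj <= ", thr$alpha,
      ", fold >= ", thr$min_fold, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.de_table <- function(object, n = 10L, ...) {
  print(object)
  rel <- object[object$relevant, , drop = FALSE]
  rel <- rel[order(rel$p_adj), , drop = FALSE]
  if (nrow(rel)) {
    cat("top relevant contigs:\n")
    print(utils::head(as.data.frame(rel), n), digits = 4)
  }
  invisible(object)
}

#' Masked log-mean matrix for heatmap display
#'
#' Rows are contigs, columns are groups; each cell is the log-transformed
#' linear group mean. Rows of contigs that are not expressed above the
#' cutoff, or not differentially expressed at biologically relevant
#' levels, are masked (set to NA) — these are the white boxes of the
#' study's expression heatmaps.
#'
#' @param x a `de_table`.
#' @param relevant_only mask everything that is not `relevant`
#'   (default TRUE).
#' @return Numeric matrix with NA in masked cells.
#' @export
heatmap_matrix <- function(x, relevant_only = TRUE) {
  stopifnot(inherits(x, "de_table"))
  groups <- attr(x, "groups")
  m <- as.matrix(x[, paste0("mean_", groups), drop = FALSE])
  m <- log(m + attr(x, "log_offset"), attr(x, "log_base"))
  dimnames(m) <- list(x$contig_id, groups)
  keep <- if (relevant_only) x$relevant else x$expressed
  m[!keep, ] <- NA_real_
  m
}
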