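#' Student-Newman-Keuls post-hoc grouping
#'
#' Step-down multiple-comparison procedure on the studentized range of the
#' ordered group means. For stretch length r = k down to 2, the range of
#' each stretch of r adjacent ordered means is compared to
#' `qtukey(1 - alpha, r, df_error) * sqrt(mse / n_h)`; a stretch whose
#' range does not reach the critical value is declared homogeneous and is
#' not subdivided further. The output is the set of homogeneous subsets
#' (possibly overlapping), reported as the usual letter groupings. With
#' unbalanced group sizes the harmonic mean of the sizes is used.
#'
#' @param means numeric vector of group means (named if letters should be
#'   reported by group name).
#' @param n group sizes: a single number for balanced designs or a vector
#'   matching `means`.
#' @param mse within-group mean square from the ANOVA; must be positive.
#' @param df_error error degrees of freedom, >= 1.
#' @param alpha significance level of each range test.
#' @return list of class `snk` with `subsets` (list of integer vectors of
#'   group indices forming homogeneous subsets), `letters` (character
#'   vector, one letter string per group, in input order), and `n_h`.
#' @export
snk_posthoc <- function(means, n, mse, df_error, alpha = 0.05) {
  k <- length(means)
  if (k < 2L) stop("need at least 2 groups")
  if (!is.finite(mse) || mse <= 0)
    stop("within-group mean square must be positive")
  if (df_error < 1) stop("df_error must be >= 1")
  if (!length(n) %in% c(1L, k)) stop("n must have length 1 or length(means)")
  if (any(n < 1)) stop("group sizes must be positive")
  n_h <- if (length(n) == 1L) n else length(n) / sum(1 / n)
  ord <- order(means)
  m <- means[ord]
  se <- sqrt(mse / n_h)

  nonsig <- list()                  # accepted (homogeneous) stretches [i, j]
  contained <- function(i, j)
    any(vapply(nonsig, function(s) i >= s[1L] && j <= s[2L], logical(1)))
  for (r in seq(k, 2L)) {
    for (i in seq_len(k - r + 1L)) {
      j <- i + r - 1L
      if (contained(i, j)) next     # inside an accepted stretch: not tested
      q_obs <- (m[j] - m[i]) / se
      if (q_obs < stats::qtukey(1 - alpha, r, df_error))
        nonsig[[length(nonsig) + 1L]] <- c(i, j)
    }
  }
  covered <- rep(FALSE, k)
  for (s in nonsig) covered[s[1L]:s[2L]] <- TRUE
  stretches <- c(nonsig, lapply(which(!covered), function(p) c(p, p)))
  stretches <- stretches[order(vapply(stretches, `[`, numeric(1), 1L),
                               vapply(stretches, `[`, numeric(1), 2L))]
  subsets <- lapply(stretches, function(s) sort(ord[s[1L]:s[2L]]))
  lab <- letters[seq_along(subsets)]
  grp_letters <- vapply(seq_len(k), function(i)
    paste(lab[vapply(subsets, function(s) i %in% s, logical(1))],
          collapse = ""), character(1))
  names(grp_letters) <- names(means)
  structure(list(subsets = subsets, letters = grp_letters, n_h = n_h,
                 alpha = alpha, df_error = df_error),
            class = "snk")
}

#' @export
print.snk <- function(x, ...) {
  cat("SNK grouping (alpha ", x$alpha, ", df ", x$df_error, "):\n", sep = "")
  nm <- names(x$letters)
  if (is.null(nm)) nm <- paste0("group", seq_along(x$letters))
  cat(paste0("  ", nm, ": ", x$letters, collapse = "\n"), "\n", sep = "")
  invisible(x)
}
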