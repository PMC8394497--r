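#' Two-sided Wilcoxon rank-sum test
#'
#' Thin, policy-carrying wrapper around the standard rank-sum test: the
#' exact null distribution is used when both groups have at most 10
#' observations and the pooled data are tie-free; otherwise the normal
#' approximation with tie and continuity corrections is used. The method
#' actually applied is recorded. Degenerate input (all pooled values
#' identical) returns p = 1 with a warning instead of NaN.
#'
#' @param x,y numeric samples (each of length >= 2), NA dropped.
#' @param exact_max largest per-group n for which the exact distribution is
#'   used (when tie-free).
#' @return list with \code{p_value}, \code{statistic} (rank-sum W of x) and
#'   \code{method} ("exact" or "normal").
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 10) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both groups; p = 1")
    return(list(p_value = 1, statistic = NA_real_, method = "degenerate"))
  }
  ties <- anyDuplicated(pooled) > 0
  use_exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE,
                       alternative = "two.sided"))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       method = if (use_exact) "exact" else "normal")
}

#' Benjamini-Hochberg step-up q-values
#'
#' Adjusts p-values for multiple comparisons by the step-up procedure
#' controlling the false-discovery rate: with ordered p-values
#' \eqn{p_{(1)} \le \dots \le p_{(m)}},
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1, mapped back to
#' the input order.
#'
#' @param p_values numeric vector in [0, 1] (NA allowed, propagated).
#' @param alpha significance level for the attached flag.
#' @return Numeric q-value vector with attribute \code{significant}
#'   (logical, \code{q < alpha}).
#' @export
benjamini_hochberg <- function(p_values, alpha = 0.05) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p_values, method = "BH")
  attr(q, "significant") <- q < alpha
  q
}

#' Kendall's tau-b between two vectors
#'
#' Tie-corrected rank correlation (the tau-b variant), used both as a
#' univariate screen against the binary class label and inside the mRMR
#' filter. Small-n direct computation over all pairs.
#'
#' @param x,y numeric vectors of equal length.
#' @return tau-b in [-1, 1] (NA if either vector is constant).
#' @export
kendall_tau_b <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  dx <- sign(outer(x, x, "-")); dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  s <- sum(dx[up] * dy[up])
  n0 <- n * (n - 1) / 2
  tx <- sum(dx[up] == 0); ty <- sum(dy[up] == 0)
  s / sqrt((n0 - tx) * (n0 - ty))
}

#' Univariate screening of a feature table
#'
#' Runs the two-sided Wilcoxon rank-sum test (MCIs vs MCIp) on every
#' feature column, applies Benjamini-Hochberg adjustment separately within
#' each feature family (neuropsych; volumes; pooled signal+texture) --
#' mirroring how such studies report neuropsychological and imaging
#' results separately -- and returns, per family, the top fraction of
#' features by raw p-value as the selection pool for the multivariate
#' stage. The default fractions (5\% of signal/texture, 15\% of volumes,
#' all neuropsych scores) reproduce a 148-of-2960 and 12-of-83 pool on the
#' full atlas.
#'
#' @param table a \code{\link{build_feature_table}} result.
#' @param top_frac named fractions per family for the selection pool.
#' @param alpha q-value significance level.
#' @return An object of class \code{univariate_screen}: \code{results}
#'   (data.frame feature/family/p/q/rank/direction/method/significant,
#'   sorted by p within family) and \code{pool} (character vector of
#'   selected column names).
#' @export
screen_features <- function(table,
                            top_frac = c(signal_texture = 0.05,
                                         volume = 0.15,
                                         neuropsych = 1.0),
                            alpha = 0.05) {
  man <- table_manifest(table)
  grp <- table$group
  stopifnot(all(grp %in% c("MCIs", "MCIp")), sum(grp == "MCIs") >= 2,
            sum(grp == "MCIp") >= 2)
  fam <- ifelse(man$family %in% c("signal", "texture"),
                "signal_texture", man$family)
  res <- lapply(seq_len(nrow(man)), function(i) {
    v <- table[[man$column[i]]]
    xs <- v[grp == "MCIs"]; xp <- v[grp == "MCIp"]
    if (sum(!is.na(xs)) < 2 || sum(!is.na(xp)) < 2 ||
        length(unique(stats::na.omit(v))) < 2) {
      return(data.frame(feature = man$column[i], family = fam[i],
                        p_value = 1, direction = "none",
                        method = "degenerate"))
    }
    w <- suppressWarnings(wilcoxon_rank_sum(xs, xp))
    dir <- if (stats::median(xp, na.rm = TRUE) >
               stats::median(xs, na.rm = TRUE)) "MCIp" else "MCIs"
    data.frame(feature = man$column[i], family = fam[i],
               p_value = w$p_value, direction = dir, method = w$method)
  })
  res <- do.call(rbind, res)
  res$q_value <- NA_real_
  for (f in unique(res$family)) {
    sel <- res$family == f
    res$q_value[sel] <- as.numeric(benjamini_hochberg(res$p_value[sel]))
  }
  res$significant <- res$q_value < alpha
  res <- res[order(res$family, res$p_value), ]
  res$rank <- stats::ave(res$p_value, res$family, FUN = rank)
  pool <- character(0)
  for (f in names(top_frac)) {
    sub <- res[res$family == f, ]
    if (nrow(sub) == 0) next
    k <- max(1L, round(top_frac[[f]] * nrow(sub)))
    pool <- c(pool, sub$feature[order(sub$p_value)][seq_len(min(k, nrow(sub)))])
  }
  rownames(res) <- NULL
  structure(list(results = res, pool = pool, top_frac = top_frac),
            class = "univariate_screen")
}

#' @export
print.univariate_screen <- function(x, ...) {
  cat(sprintf("univariate_screen: %d features tested, %d significant (q < 0.05), pool of %d\n",
              nrow(x$results), sum(x$results$significant, na.rm = TRUE),
              length(x$pool)))
  top <- utils::head(x$results[order(x$results$p_value), ], 5)
  cat("top features:\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-45s p = %.3g  q = %.3g\n", top$feature[i],
                top$p_value[i], top$q_value[i]))
  invisible(x)
}

#' Demographic group comparisons
#'
#' Age and years of education are compared with the Wilcoxon rank-sum test;
#' the male/female proportion with a chi-squared test (Yates continuity
#' correction) on the 2 x 2 sex-by-group table.
#'
#' @param cohort data.frame with columns \code{group} ("MCIs"/"MCIp"),
#'   \code{age}, \code{education}, \code{sex} ("M"/"F").
#' @return Named list of p-values: \code{age}, \code{education}, \code{sex},
#'   plus the \code{sex_table}.
#' @export
demographics_tests <- function(cohort) {
  stopifnot(all(c("group", "age", "education", "sex") %in% names(cohort)))
  g <- factor(cohort$group, levels = c("MCIs", "MCIp"))
  if (any(table(g) == 0)) stop("both groups must be present")
  tab <- table(g, factor(cohort$sex, levels = c("M", "F")))
  if (any(rowSums(tab) == 0)) stop("empty group row in sex table")
  sex_p <- suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
  list(age = wilcoxon_rank_sum(cohort$age[g == "MCIs"],
                               cohort$age[g == "MCIp"])$p_value,
       education = wilcoxon_rank_sum(cohort$education[g == "MCIs"],
                                     cohort$education[g == "MCIp"])$p_value,
       sex = sex_p, sex_table = tab)
}
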