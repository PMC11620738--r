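#' Reconstruct an integer count from a rounded percentage
#'
#' Published penetrance tables print a percentage and the number of
#' animals scored; the underlying integer count is recovered as the
#' `c in 0..n` minimizing `|pct - 100 * c / n|`, ties broken toward the
#' smaller count.  If even the best candidate misses the printed value by
#' more than `tol` percentage points (one-decimal rounding can contribute
#' at most 0.05; the default 0.15 also absorbs small transcription
#' artifacts), a warning is raised — not an error, since the printed value
#' is the only evidence available.
#'
#' @param pct printed percentage, in \[0, 100\].
#' @param n number of animals scored (>= 1).
#' @param tol warning threshold in percentage points.
#' @return the reconstructed integer count.
#' @examples
#' reconstruct_count(4.7, 107)   # 5  (5/107 = 4.67%)
#' reconstruct_count(45.8, 94)   # 43 (43/94 = 45.74%)
#' @export
reconstruct_count <- function(pct, n, tol = 0.15) {
  stopifnot(length(pct) == 1L, length(n) == 1L)
  if (!is.finite(pct) || pct < 0 || pct > 100) {
    stop("pct must lie in [0, 100]", call. = FALSE)
  }
  n <- as.integer(n)
  if (n < 1L) stop("n must be a positive integer", call. = FALSE)
  cand <- 0:n
  disc <- abs(pct - 100 * cand / n)
  best <- cand[which.min(disc)]  # which.min takes the first, i.e. smaller c
  if (min(disc) > tol) {
    warning(sprintf(
      "reconstructed count %d/%d = %.4g%% differs from printed %.4g%% by %.3g points",
      best, n, 100 * best / n, pct, min(disc)), call. = FALSE)
  }
  best
}

.new_test_result <- function(statistic, df, p_value, method, extra = list()) {
  structure(c(list(statistic = statistic, df = df, p_value = p_value,
                   method = method), extra),
            class = "pola_test")
}

#' @export
print.pola_test <- function(x, ...) {
  lbl <- switch(x$method, pearson_chi2 = "Pearson chi-square",
                student_t = "Student t (pooled)", welch_t = "Welch t",
                x$method)
  cat(sprintf("%s: statistic = %.6g, df = %s, p = %.4g\n", lbl,
              x$statistic, format(x$df), x$p_value))
  if (!is.null(x$counts)) {
    cat("counts:\n"); print(x$counts)
  }
  invisible(x)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' The plain Pearson statistic `sum((O - E)^2 / E)` with `df = 1` and no
#' continuity correction, with the p-value from the upper chi-square tail.
#' Rows are groups (e.g. genotypes), columns outcome present/absent.
#'
#' @param table a 2x2 numeric matrix of non-negative counts; both row sums
#'   must be positive.  A zero column sum yields statistic 0, p = 1, with
#'   a warning (no association is estimable).
#' @return a `pola_test` result with fields `statistic`, `df`, `p_value`,
#'   `method`, `counts`.
#' @examples
#' pearson_chi2(matrix(c(5, 43, 102, 51), nrow = 2))
#' @export
pearson_chi2 <- function(table) {
  x <- as.matrix(table)
  if (!all(dim(x) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(x < 0) || any(!is.finite(x))) {
    stop("counts must be non-negative and finite", call. = FALSE)
  }
  if (any(rowSums(x) == 0)) {
    stop("degenerate table: a row sum is zero", call. = FALSE)
  }
  if (any(colSums(x) == 0)) {
    warning("a column sum is zero; statistic is 0", call. = FALSE)
    return(.new_test_result(0, 1L, 1, "pearson_chi2", list(counts = x)))
  }
  expected <- outer(rowSums(x), colSums(x)) / sum(x)
  stat <- sum((x - expected)^2 / expected)
  .new_test_result(stat, 1L, pchisq(stat, df = 1L, lower.tail = FALSE),
                   "pearson_chi2", list(counts = x))
}

#' Two-sample Student t-test on residual distributions
#'
#' Classical pooled-variance two-sided t-test, `df = nA + nB - 2`, used to
#' compare signed or absolute residual distributions between genotypes.
#' Welch's unequal-variance variant is available behind a flag but the
#' pooled test is the default.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @param welch use the Welch approximation instead of pooling.
#' @return a `pola_test` result.
#' @export
student_t <- function(group_a, group_b, welch = FALSE) {
  a <- group_a[is.finite(group_a)]; b <- group_b[is.finite(group_b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  va <- var(a); vb <- var(b)
  if (welch) {
    se2 <- va / na + vb / nb
    if (se2 <= 0) stop("degenerate: zero variance in both groups",
                       call. = FALSE)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    stat <- (mean(a) - mean(b)) / sqrt(se2)
    method <- "welch_t"
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 <= 0) stop("degenerate: zero pooled variance", call. = FALSE)
    df <- na + nb - 2L
    stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    method <- "student_t"
  }
  .new_test_result(stat, df, 2 * pt(abs(stat), df = df, lower.tail = FALSE),
                   method)
}

#' Penetrance enhancement test between two genotypes
#'
#' Builds the 2x2 table (phenotype missing vs present, by genotype) for
#' one gonadal region from a penetrance table and runs [pearson_chi2()].
#' Counts come from the `count_missing` column when present, otherwise
#' they are reconstructed from the printed percentage via
#' [reconstruct_count()]; the counts used are reported alongside the test
#' for auditability.
#'
#' @param records a phenotype `data.frame`
#'   (see [read_phenotype_table()]).
#' @param genotype_a,genotype_b the two genotype labels to compare.
#' @param region `"anterior"` or `"posterior"`.
#' @return a `pola_test` with the 2x2 `counts` attached (rows named by
#'   genotype; columns `missing`, `present`).
#' @examples
#' tab <- data.frame(
#'   genotype = c("g1", "g2"), region = "anterior",
#'   pct_missing = c(4.7, 45.8), n = c(107L, 94L))
#' enhancement_test(tab, "g1", "g2", "anterior")
#' @export
enhancement_test <- function(records, genotype_a, genotype_b, region) {
  records <- validate_phenotype_table(records)
  region <- match.arg(region, .pola_regions)
  pick <- function(g) {
    row <- records[records$genotype == g & records$region == region, ,
                   drop = FALSE]
    if (nrow(row) == 0L) {
      stop("no record for genotype '", g, "' in region '", region, "'",
           call. = FALSE)
    }
    row <- row[1L, ]
    miss <- if ("count_missing" %in% names(row) && !is.na(row$count_missing))
      row$count_missing else reconstruct_count(row$pct_missing, row$n)
    c(missing = miss, present = row$n - miss)
  }
  counts <- rbind(pick(genotype_a), pick(genotype_b))
  rownames(counts) <- c(genotype_a, genotype_b)
  res <- pearson_chi2(counts)
  res$counts <- counts
  res
}
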