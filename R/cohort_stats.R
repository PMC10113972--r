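#' Summary statistic triple
#'
#' Mean, standard deviation and sample size of one group; the unit of
#' account for summary-level tests when only published tables are
#' available.
#'
#' @param mean group mean.
#' @param sd group standard deviation, > 0.
#' @param n group size, >= 2.
#' @return A `summary_stat`.
#' @export
summary_stat <- function(mean, sd, n) {
  if (!is.finite(sd) || sd <= 0)
    cv_stop("cv_domain_error", "sd must be > 0")
  n <- as.integer(n)
  if (is.na(n) || n < 2L)
    cv_stop("cv_domain_error", "n must be at least 2")
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd), n = n),
            class = "summary_stat")
}

summarize_sample <- function(x) summary_stat(mean(x), sd(x), length(x))

test_result <- function(statistic, df, p, method) {
  structure(list(statistic = as.numeric(statistic),
                 df = if (is.null(df)) NA_real_ else as.numeric(df),
                 p_two_sided = min(max(as.numeric(p), 0), 1),
                 method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, df %.4g, two-sided p %.4g\n",
              x$method, x$statistic, x$df, x$p_two_sided))
  invisible(x)
}

#' Two-sample t test from summary statistics
#'
#' Welch's unequal-variance form by default:
#' `t = (m_a - m_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with Welch-Satterthwaite
#' degrees of freedom. The pooled-variance form is available via
#' `pooled = TRUE`. Welch is the default because published p-values from
#' unequal-spread trauma subgroups are reproduced far better without the
#' equal-variance assumption.
#'
#' @param a,b [summary_stat()]s.
#' @param pooled use the pooled-variance (Student) form.
#' @return A `test_result`.
#' @export
welch_t_summary <- function(a, b, pooled = FALSE) {
  stopifnot(inherits(a, "summary_stat"), inherits(b, "summary_stat"))
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  if (pooled) {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
    method <- "Student t (pooled, summary)"
  } else {
    t <- (a$mean - b$mean) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    method <- "Welch t (summary)"
  }
  test_result(t, df, 2 * pt(-abs(t), df), method)
}

#' Two-sample t test from raw data
#'
#' Computes the group summaries and delegates to [welch_t_summary()], so
#' the raw-data and summary-statistic routes agree exactly by contract.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param pooled use the pooled-variance form.
#' @return A `test_result`.
#' @export
welch_t_data <- function(x, y, pooled = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    cv_stop("cv_domain_error", "each sample needs at least 2 observations")
  welch_t_summary(summarize_sample(x), summarize_sample(y), pooled = pooled)
}

#' Mann-Whitney U test
#'
#' For combined sample sizes up to 30 the exact permutation distribution of
#' the rank sum is computed (dynamic programming over the pooled midranks,
#' equivalent to enumerating all arrangements, and valid under ties); the
#' two-sided p-value is `min(1, 2 * min(P(W <= w), P(W >= w)))`. Larger
#' samples use the normal approximation with tie and continuity
#' corrections.
#'
#' @param x,y numeric samples (each non-empty).
#' @return A `test_result`; the statistic is the U of the first sample.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L)
    cv_stop("cv_domain_error", "both samples must be non-empty")
  m <- as.numeric(length(x)); n <- as.numeric(length(y)); N <- m + n
  pooled <- c(x, y)
  r <- rank(pooled)                      # midranks
  w <- sum(r[seq_len(m)])
  u <- w - m * (m + 1) / 2
  if (N <= 30L) {
    r2 <- as.integer(round(2 * r))       # integerize midranks
    # f[k+1, s+1] = number of m-subsets of size k with doubled rank sum s
    smax <- sum(sort(r2, decreasing = TRUE)[seq_len(m)])
    f <- matrix(0, nrow = m + 1, ncol = smax + 1)
    f[1, 1] <- 1
    for (ri in r2) {
      kmax <- m
      for (k in kmax:1) {
        src <- f[k, ]
        idx <- which(src > 0)
        if (length(idx) > 0) {
          tgt <- idx + ri
          ok <- tgt <= smax + 1
          f[k + 1, tgt[ok]] <- f[k + 1, tgt[ok]] + src[idx[ok]]
        }
      }
    }
    dist <- f[m + 1, ]
    total <- sum(dist)                    # = choose(N, m)
    w2 <- as.integer(round(2 * w))
    p_le <- sum(dist[seq_len(min(w2 + 1, length(dist)))]) / total
    p_ge <- sum(dist[(w2 + 1):length(dist)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "Mann-Whitney U (exact permutation)"
  } else {
    mu <- m * n / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- m * n / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  test_result(u, NA_real_, p, method)
}

check_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    cv_stop("cv_domain_error", "table must be 2x2")
  if (any(tab < 0) || any(abs(tab - round(tab)) > 1e-8))
    cv_stop("cv_domain_error", "table entries must be non-negative integers")
  round(tab)
}

#' Pearson chi-square test for a 2x2 table
#'
#' `sum((O - E)^2 / E)` with df = 1, optionally with the Yates continuity
#' correction. All four marginals must be positive.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param yates apply the continuity correction.
#' @return A `test_result`.
#' @export
chi_square_2x2 <- function(tab, yates = FALSE) {
  tab <- check_2x2(tab)
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  if (any(rs == 0) || any(cs == 0))
    cv_stop("cv_domain_error", "degenerate table: a marginal total is zero")
  E <- outer(rs, cs) / N
  dev <- abs(tab - E)
  if (yates) dev <- pmax(dev - 0.5, 0)
  x2 <- sum(dev^2 / E)
  test_result(x2, 1, pchisq(x2, df = 1, lower.tail = FALSE),
              if (yates) "Pearson chi-square (Yates)" else "Pearson chi-square")
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided by the minimum-likelihood convention: with all margins fixed,
#' the p-value sums the hypergeometric probabilities of every admissible
#' table whose point probability does not exceed that of the observed
#' table (within a 1e-7 relative tolerance). Degenerate margins (only one
#' admissible table) give p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return A `test_result`; the statistic is the observed top-left count.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- check_2x2(tab)
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a <- tab[1, 1]
  kmin <- max(0, c1 - r2); kmax <- min(r1, c1)
  kk <- kmin:kmax
  probs <- dhyper(kk, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  p <- if (length(kk) == 1L) 1 else sum(probs[probs <= p_obs * (1 + 1e-7)])
  test_result(a, NA_real_, p, "Fisher exact (two-sided, minimum likelihood)")
}

#' Empirical ROC curve, AUC and Youden-optimal threshold
#'
#' The curve is evaluated at every distinct score (rule: predict positive
#' when the oriented score is at or above the threshold) plus sentinels at
#' both ends. The AUC is computed by the Mann-Whitney identity with ties
#' credited one half, which equals the trapezoidal area under the stored
#' curve. The Youden-optimal threshold maximizes
#' `sensitivity + specificity - 1`; ties break toward the threshold with
#' the higher sensitivity.
#'
#' When the score runs opposite to risk (e.g. percentage of *normal* lung
#' rather than contused lung), set `higher_is_positive = FALSE`: the score
#' is negated internally and thresholds are reported on the caller's
#' scale.
#'
#' @param scores numeric predictor values.
#' @param labels logical (TRUE = diseased/positive) of the same length.
#' @param higher_is_positive orientation of the score.
#' @return An `roc_result`: `curve` (threshold, sensitivity, specificity),
#'   `auc`, `youden_threshold`, `sens_at_youden`, `spec_at_youden`.
#' @export
roc_empirical <- function(scores, labels, higher_is_positive = TRUE) {
  if (length(scores) != length(labels))
    cv_stop("cv_domain_error", "scores and labels must have equal length")
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.logical(labels[keep])
  n1 <- as.numeric(sum(labels)); n0 <- as.numeric(sum(!labels))
  if (n1 == 0L || n0 == 0L)
    cv_stop("cv_domain_error", "both classes must be present in labels")
  s <- if (higher_is_positive) scores else -scores
  # AUC by the rank (Mann-Whitney) identity, ties counted half
  r <- rank(s)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(s))
  sens <- vapply(thr, function(t) mean(s[labels] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(s[!labels] < t), numeric(1))
  thr <- c(-Inf, thr, Inf)
  sens <- c(1, sens, 0)
  spec <- c(0, spec, 1)
  youden <- sens + spec - 1
  best <- which(youden == max(youden))[1]   # smallest threshold = higher sens
  to_user <- function(t) if (higher_is_positive) t else -t
  curve <- data.frame(threshold = to_user(thr), sensitivity = sens,
                      specificity = spec)
  structure(list(
    curve = curve, auc = auc,
    youden_threshold = to_user(thr[best]),
    sens_at_youden = sens[best], spec_at_youden = spec[best],
    higher_is_positive = higher_is_positive,
    n_positive = n1, n_negative = n0
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.3f (%d pos / %d neg)\n", x$auc,
              x$n_positive, x$n_negative))
  cat(sprintf("  Youden threshold %.4g: sensitivity %.3f, specificity %.3f\n",
              x$youden_threshold, x$sens_at_youden, x$spec_at_youden))
  invisible(x)
}

#' Percentile-bootstrap confidence interval for the empirical AUC
#'
#' Stratified resampling within each class. Provided for reporting
#' completeness; the interval method used for the published CI is unknown,
#' so this is not validated against it.
#'
#' @param scores,labels as in [roc_empirical()].
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @return `c(lower, upper)`.
#' @export
roc_auc_ci_boot <- function(scores, labels, n_boot = 2000L, conf = 0.95) {
  labels <- as.logical(labels)
  ip <- which(labels); im <- which(!labels)
  aucs <- vapply(seq_len(n_boot), function(i) {
    bi <- c(sample(ip, length(ip), replace = TRUE),
            sample(im, length(im), replace = TRUE))
    roc_empirical(scores[bi], labels[bi])$auc
  }, numeric(1))
  unname(stats::quantile(aucs, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
}

#' Binormal AUC from group summaries
#'
#' Closed-form ROC area under two normal score distributions:
#' `Phi((m_a - m_b) / sqrt(s_a^2 + s_b^2))`, where group `a` is the
#' diseased/positive one. Equals 0.5 when the means coincide. Used to
#' validate discrimination claims when only summary tables are available.
#'
#' @param a diseased-group [summary_stat()].
#' @param b control-group [summary_stat()].
#' @return AUC in (0, 1).
#' @export
binormal_auc <- function(a, b) {
  stopifnot(inherits(a, "summary_stat"), inherits(b, "summary_stat"))
  pnorm((a$mean - b$mean) / sqrt(a$sd^2 + b$sd^2))
}

#' Age adjustment by pooled-regression residuals
#'
#' Fits one ordinary-least-squares line of `score` on `age` over all
#' patients pooled, takes residuals, summarizes them per group
#' (mean +/- SD) and compares the groups with a Welch t test on the
#' residuals. This is the standard residualization route for removing a
#' shared age trend before a two-group comparison.
#'
#' @param score numeric outcome/predictor to adjust.
#' @param age numeric age (years).
#' @param group two-level factor/character of group membership.
#' @return An `age_adjust_result`: `slope`, `intercept`, `residuals`,
#'   per-group [summary_stat()]s, and the Welch `test` on residuals.
#' @export
age_adjust_residuals <- function(score, age, group) {
  if (length(score) < 3L || length(age) != length(score) ||
      length(group) != length(score))
    cv_stop("cv_domain_error", "need at least 3 complete (score, age, group) rows")
  group <- as.character(group)
  lv <- unique(group)
  if (length(lv) != 2L)
    cv_stop("cv_domain_error", "exactly two groups are required (got %d)", length(lv))
  if (sd(age) == 0)
    cv_stop("cv_domain_error", "age is constant; regression fit is singular")
  fit <- lm(score ~ age)
  res <- residuals(fit)
  g1 <- res[group == lv[1]]; g2 <- res[group == lv[2]]
  if (length(g1) < 2L || length(g2) < 2L)
    cv_stop("cv_domain_error", "each group needs at least 2 rows")
  s1 <- summarize_sample(g1); s2 <- summarize_sample(g2)
  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    residuals = res,
    groups = stats::setNames(list(s1, s2), lv),
    test = welch_t_summary(s1, s2)
  ), class = "age_adjust_result")
}

#' Cohort analysis report
#'
#' Reproduces the study-style battery on a cohort table: severity-group
#' comparison (age by Welch t; pneumonia, ARDS and mortality as 2x2
#' tables, Pearson chi-square when all expected cells are at least 5 and
#' Fisher exact otherwise, with both reported), pneumonia-group t tests
#' (GCS, ISS, lactate, contusion ratio), empirical ROC of the contusion
#' ratio for pneumonia with the Youden threshold reported both as a
#' contusion-ratio and a normal-lung percentage, the summary-level
#' binormal AUC, and the age-residual adjustment of the contusion ratio
#' across severity groups. No multiple-testing correction is applied;
#' p-values are raw.
#'
#' @param tab a `cohort_table` (e.g. from [simulate_cohort()] or
#'   [cohort_from_csv()]).
#' @return A `cohort_report` list.
#' @export
cohort_analyze <- function(tab) {
  stopifnot(is.data.frame(tab))
  missing_cols <- setdiff(required_cohort_columns, names(tab))
  if (length(missing_cols) > 0)
    cv_stop("cv_schema_error", "cohort table is missing columns: %s",
            paste(missing_cols, collapse = ", "))
  sev <- tab$severity == "severe"
  pne <- as.logical(tab$pneumonia)
  group_2x2 <- function(event) {
    # rows: moderate, severe; cols: event yes, no
    m <- matrix(c(sum(event & !sev), sum(!event & !sev),
                  sum(event & sev), sum(!event & sev)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("moderate", "severe"), c("yes", "no")))
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    chi <- if (any(rowSums(m) == 0) || any(colSums(m) == 0)) NULL
           else chi_square_2x2(m)
    list(table = m,
         chi_square = chi,
         fisher = fisher_exact_2x2(m),
         recommended = if (!is.null(chi) && all(E >= 5)) "chi_square" else "fisher")
  }
  t_by_pneumonia <- function(col) {
    x <- tab[[col]][pne]; y <- tab[[col]][!pne]
    if (length(x) < 2L || length(y) < 2L) return(NULL)
    list(pneumonia = unclass(summarize_sample(x)),
         no_pneumonia = unclass(summarize_sample(y)),
         welch = welch_t_data(x, y),
         mann_whitney = mann_whitney(x, y))
  }
  both_pne <- length(unique(pne)) == 2L
  roc <- if (both_pne) roc_empirical(tab$contusion_ratio, pne) else NULL
  bin_auc <- if (both_pne && sum(pne) >= 2 && sum(!pne) >= 2)
    binormal_auc(summarize_sample(tab$contusion_ratio[pne]),
                 summarize_sample(tab$contusion_ratio[!pne])) else NULL
  both_sev <- length(unique(sev)) == 2L
  report <- list(
    n = nrow(tab),
    counts = list(
      pneumonia = sum(pne), ards = sum(tab$ards), mortality = sum(tab$mortality),
      moderate = sum(!sev), severe = sum(sev)
    ),
    percents = list(
      pneumonia = 100 * mean(pne),
      ards = 100 * mean(tab$ards),
      mortality = 100 * mean(tab$mortality)
    ),
    severity_groups = if (both_sev) list(
      age = list(
        moderate = unclass(summarize_sample(tab$age[!sev])),
        severe = unclass(summarize_sample(tab$age[sev])),
        welch = welch_t_data(tab$age[sev], tab$age[!sev])
      ),
      pneumonia = group_2x2(pne),
      ards = group_2x2(as.logical(tab$ards)),
      mortality = group_2x2(as.logical(tab$mortality)),
      age_adjusted_ratio = age_adjust_residuals(tab$contusion_ratio, tab$age,
                                                tab$severity)
    ) else NULL,
    pneumonia_groups = if (both_pne) list(
      gcs = t_by_pneumonia("gcs"),
      iss = t_by_pneumonia("iss"),
      lactate = t_by_pneumonia("lactate"),
      contusion_ratio = t_by_pneumonia("contusion_ratio")
    ) else NULL,
    roc = if (!is.null(roc)) list(
      auc = roc$auc,
      binormal_auc = bin_auc,
      youden_threshold_contusion_pct = roc$youden_threshold,
      youden_threshold_normal_lung_pct = 100 - roc$youden_threshold,
      sensitivity = roc$sens_at_youden,
      specificity = roc$spec_at_youden
    ) else NULL,
    notes = c(
      "p-values are raw; no multiple-testing correction (matching source methodology)",
      "2x2 recommendation: chi-square when all expected cells >= 5, else Fisher"
    )
  )
  structure(report, class = "cohort_report")
}

#' Write a cohort report and its ROC curve
#'
#' @param report a `cohort_report`.
#' @param path JSON destination; an `<path>_roc.csv` sidecar is written
#'   when `roc_curve` is supplied.
#' @param roc_curve optional `roc_result` whose curve to write.
#' @export
write_cohort_report <- function(report, path, roc_curve = NULL) {
  stopifnot(inherits(report, "cohort_report"))
  clean <- rapply(unclass(report), unclass, how = "replace")
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  if (!is.null(roc_curve)) {
    write.csv(roc_curve$curve,
              sub("\\.json$", "_roc.csv", path), row.names = FALSE)
  }
  invisible(path)
}
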