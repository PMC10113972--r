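test_that("welch_t_summary matches quadrature and published-table behaviour", {
  s <- summary_stat(5, 2, 20)
  same <- welch_t_summary(s, s)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_two_sided, 1)
  # quadrature oracle: integrate the t density beyond |t| at the Welch df
  r <- welch_t_summary(summary_stat(1, 1, 10), summary_stat(0, 1, 10))
  oracle <- 2 * integrate(function(x) dt(x, df = r$df), abs(r$statistic),
                          Inf)$value
  expect_equal(r$p_two_sided, oracle, tolerance = 1e-8)
  # published contusion-ratio row: strongly significant
  tab3 <- welch_t_summary(summary_stat(33.04, 11.4, 28),
                          summary_stat(18.3, 8.5, 45))
  expect_lt(tab3$p_two_sided, 1e-4)
  expect_error(welch_t_summary(summary_stat(1, 0, 10), s),
               class = "cv_domain_error")
  expect_error(summary_stat(1, 1, 1), class = "cv_domain_error")
})

test_that("raw-data t test equals the summary route and t.test", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    via_data <- welch_t_data(x, y)
    via_summary <- welch_t_summary(
      summary_stat(mean(x), sd(x), length(x)),
      summary_stat(mean(y), sd(y), length(y)))
    expect_equal(via_data$p_two_sided, via_summary$p_two_sided)
    expect_equal(via_data$statistic, via_summary$statistic)
    expect_equal(via_data$p_two_sided, t.test(x, y)$p.value, tolerance = 1e-12)
    expect_equal(welch_t_data(x, y, pooled = TRUE)$p_two_sided,
                 t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-12)
  }
  expect_error(welch_t_data(1, c(1, 2)), class = "cv_domain_error")
})

test_that("Mann-Whitney exact path equals brute-force enumeration", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$p_two_sided, 1 / 3)
  expect_equal(mann_whitney(c(1, 2, 5), c(1, 2, 5))$p_two_sided, 1)
  brute <- function(x, y) {
    pooled <- c(x, y); m <- length(x)
    r <- rank(pooled); w_obs <- sum(r[seq_len(m)])
    ws <- apply(combn(length(pooled), m), 2, function(ix) sum(r[ix]))
    min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
  }
  set.seed(32)
  for (i in 1:15) {
    x <- sample(1:8, sample(2:6, 1), replace = TRUE)   # ties likely
    y <- sample(1:8, sample(2:6, 1), replace = TRUE)
    expect_equal(mann_whitney(x, y)$p_two_sided, brute(x, y))
  }
  # tie-free exact case agrees with wilcox.test's exact distribution
  x <- c(1.1, 3.2, 5.5, 7.1); y <- c(2.2, 4.9, 8.3, 9.0, 10.5)
  expect_equal(mann_whitney(x, y)$p_two_sided,
               wilcox.test(x, y, exact = TRUE)$p.value)
  # large-sample approximation with ties matches the reference correction
  set.seed(33)
  xt <- round(rnorm(25), 1); yt <- round(rnorm(20, 0.4), 1)
  expect_equal(mann_whitney(xt, yt)$p_two_sided,
               wilcox.test(xt, yt, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
  expect_error(mann_whitney(numeric(0), 1), class = "cv_domain_error")
})

test_that("2x2 chi-square equals the four-term loop and flags degeneracy", {
  flat <- chi_square_2x2(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_two_sided, 1)
  # published pneumonia table: moderate 5/30, severe 23/15
  pneu <- chi_square_2x2(matrix(c(5, 23, 30, 15), 2))
  expect_lt(pneu$p_two_sided, 0.005)
  set.seed(34)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 9) + 1, 2)
    # independent four-term loop
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    x2 <- 0
    for (r in 1:2) for (c in 1:2) x2 <- x2 + (tab[r, c] - E[r, c])^2 / E[r, c]
    got <- chi_square_2x2(tab)
    expect_equal(got$statistic, x2, tolerance = 1e-12)
    expect_equal(got$p_two_sided, pchisq(x2, 1, lower.tail = FALSE))
    expect_equal(chi_square_2x2(tab, yates = TRUE)$p_two_sided,
                 suppressWarnings(chisq.test(tab, correct = TRUE)$p.value),
                 tolerance = 1e-12)
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)),
               class = "cv_domain_error")
  expect_error(chi_square_2x2(matrix(c(-1, 2, 3, 4), 2)),
               class = "cv_domain_error")
})

test_that("Fisher exact matches hypergeometric enumeration and fisher.test", {
  # enumeration oracle written out longhand over all admissible tables
  enum_fisher <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
    ks <- max(0, c1 - r2):min(r1, c1)
    prob <- function(a) {
      choose(r1, a) * choose(r2, c1 - a) / choose(N, c1)
    }
    probs <- vapply(ks, prob, numeric(1))
    p_obs <- prob(tab[1, 1])
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  ards <- matrix(c(0, 5, 35, 33), 2)   # published ARDS counts by severity
  expect_equal(fisher_exact_2x2(ards)$p_two_sided, enum_fisher(ards))
  set.seed(35)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p_two_sided, enum_fisher(tab),
                 tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab)$p_two_sided,
                 fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  # hypergeometric completeness: admissible-table probabilities sum to 1
  for (i in 1:10) {
    tab <- matrix(rpois(4, 5) + 1, 2)
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    ks <- max(0, c1 - r2):min(r1, c1)
    expect_equal(sum(dhyper(ks, r1, r2, c1)), 1, tolerance = 1e-12)
  }
  # degenerate margins: single admissible table, p = 1
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2))$p_two_sided, 1)
})

test_that("empirical ROC equals the pairwise Mann-Whitney oracle", {
  perfect <- roc_empirical(c(1, 2, 3, 10, 11, 12),
                           c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(perfect$auc, 1.0)
  expect_equal(perfect$sens_at_youden, 1.0)
  expect_equal(perfect$spec_at_youden, 1.0)
  flat <- roc_empirical(rep(5, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(flat$auc, 0.5)
  set.seed(36)
  for (i in 1:10) {
    scores <- round(rnorm(20), 1)
    labels <- runif(20) < 0.4
    if (length(unique(labels)) < 2) next
    r <- roc_empirical(scores, labels)
    # all-pairs count, ties credited one half
    pos <- scores[labels]; neg <- scores[!labels]
    u <- 0
    for (p in pos) for (q in neg) u <- u + (p > q) + 0.5 * (p == q)
    expect_equal(r$auc, u / (length(pos) * length(neg)))
    # AUC identity with the trapezoidal area of the stored curve
    fpr <- 1 - r$curve$specificity; tpr <- r$curve$sensitivity
    ord <- order(fpr, tpr)
    trap <- sum(diff(fpr[ord]) * (head(tpr[ord], -1) + tail(tpr[ord], -1)) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
    # sensitivity is non-increasing in the threshold
    expect_true(all(diff(r$curve$sensitivity) <= 0))
  }
  expect_error(roc_empirical(1:5, rep(TRUE, 5)), class = "cv_domain_error")
})

test_that("score orientation is handled and thresholds reported on the user scale", {
  set.seed(37)
  scores <- rnorm(40, ifelse(runif(40) < 0.5, 2, 0))
  labels <- scores + rnorm(40, sd = 0.5) > 1
  if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
  up <- roc_empirical(scores, labels)
  # "normal lung percent" style: the same information, negated
  down <- roc_empirical(-scores, labels, higher_is_positive = FALSE)
  expect_equal(down$auc, up$auc)
  expect_equal(down$youden_threshold, -up$youden_threshold)
  expect_equal(down$sens_at_youden, up$sens_at_youden)
})

test_that("binormal AUC matches its closed form and the empirical curve", {
  expect_equal(binormal_auc(summary_stat(5, 2, 10), summary_stat(5, 3, 10)), 0.5)
  expect_gt(binormal_auc(summary_stat(10, 1, 10), summary_stat(0, 1, 10)),
            0.9999)
  # published summary parameters round to the published discrimination
  auc <- binormal_auc(summary_stat(33.04, 11.4, 28), summary_stat(18.3, 8.5, 45))
  expect_equal(round(auc, 2), 0.85)
  # large-simulation agreement between the binormal and empirical routes
  set.seed(38)
  n <- 50000
  a <- rnorm(n, 33.04, 11.4); b <- rnorm(n, 18.3, 8.5)
  emp <- roc_empirical(c(a, b), rep(c(TRUE, FALSE), each = n))$auc
  expect_lt(abs(emp - auc), 0.01)
})

test_that("age adjustment by pooled OLS residuals behaves like OLS", {
  # exactly linear score: all residuals vanish
  age <- c(20, 30, 40, 50, 60, 70)
  lin <- age_adjust_residuals(2 + 0.5 * age, age,
                              rep(c("a", "b"), 3))
  expect_lt(max(abs(lin$residuals)), 1e-10)
  expect_equal(lin$groups$a$mean, 0, tolerance = 1e-10)
  set.seed(39)
  score <- rnorm(50, 10 + 0.3 * (1:50))
  res <- age_adjust_residuals(score, 1:50, rep(c("m", "s"), 25))
  expect_equal(sum(res$residuals), 0, tolerance = 1e-9)   # OLS identity
  # Welch test on residuals equals a manual Welch on the same residuals
  manual <- welch_t_data(res$residuals[rep(c(TRUE, FALSE), 25)],
                         res$residuals[rep(c(FALSE, TRUE), 25)])
  expect_equal(res$test$p_two_sided, manual$p_two_sided)
  # slope recovery on a generated age trend (0.4 points per year)
  set.seed(40)
  n <- 10000
  agev <- runif(n, 20, 80)
  grp <- rep(c("m", "s"), n / 2)
  sc <- 5 + 0.4 * agev + rnorm(n, sd = 8) + ifelse(grp == "s", 4, 0)
  fit <- age_adjust_residuals(sc, agev, grp)
  expect_lt(abs(fit$slope - 0.4), 0.05)
  expect_error(age_adjust_residuals(sc, rep(50, n), grp),
               class = "cv_domain_error")
  expect_error(age_adjust_residuals(sc[1:10], agev[1:10], rep("m", 10)),
               class = "cv_domain_error")
})

test_that("cohort_analyze assembles the full battery on a simulated cohort", {
  tab <- simulate_cohort(cohort_config(n = 400, seed = 9))
  report <- cohort_analyze(tab)
  expect_equal(report$n, 400L)
  expect_equal(report$counts$moderate + report$counts$severe, 400)
  expect_gt(report$roc$auc, 0.7)     # built-in group separation is strong
  expect_equal(report$roc$youden_threshold_normal_lung_pct,
               100 - report$roc$youden_threshold_contusion_pct)
  expect_lt(report$pneumonia_groups$contusion_ratio$welch$p_two_sided, 1e-6)
  expect_s3_class(report$severity_groups$pneumonia$fisher, "test_result")
  expect_true(report$severity_groups$pneumonia$recommended %in%
                c("chi_square", "fisher"))
  expect_equal(sum(report$severity_groups$age_adjusted_ratio$residuals), 0,
               tolerance = 1e-6)
  # serialization round trip
  path <- tempfile(fileext = ".json")
  write_cohort_report(report, path,
                      roc_curve = roc_empirical(tab$contusion_ratio,
                                                tab$pneumonia))
  back <- jsonlite::read_json(path)
  expect_equal(back$roc$auc, report$roc$auc, tolerance = 1e-12)
  expect_true(file.exists(sub("\\.json$", "_roc.csv", path)))
})
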