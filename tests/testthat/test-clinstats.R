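test_that("correlations match hand-computed values", {
  x <- c(1, 2, 3); y <- c(6, 4, 5)
  expect_equal(correlate(x, x)$coefficient, 1)
  expect_equal(correlate(x, y, "spearman")$coefficient, -0.5)
  set.seed(2)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(correlate(a, b, "pearson")$coefficient, cor(a, b))
  expect_error(correlate(c(1, 1, 1), y), "constant")
  expect_error(correlate(1:2, 1:2), "length")
})

test_that("quartile assignment splits evenly and breaks ties downward", {
  q <- assign_quartiles(1:8)
  expect_identical(as.integer(table(q)), rep(2L, 4))
  expect_identical(as.character(q), rep(paste0("Q", 1:4), each = 2))
  # 230 distinct values: group sizes within 1 of 57.5
  set.seed(9)
  v <- sample(seq_len(1000), 230)
  sizes <- as.integer(table(assign_quartiles(v)))
  expect_true(all(abs(sizes - 57.5) <= 1))
  # ties at a threshold fall into the lower quartile
  vals <- c(1, 2, 2, 2, 3, 4, 5, 6)
  q2 <- assign_quartiles(vals)
  expect_true(all(q2[vals == 2] == q2[2]))
  expect_error(assign_quartiles(rep(3, 10)), "degenerate")
  expect_error(assign_quartiles(1:3), "at least 4")
})

test_that("quartile labels are equivariant under permutation", {
  set.seed(11)
  v <- rnorm(40)
  q <- assign_quartiles(v)
  perm <- sample(40)
  expect_identical(assign_quartiles(v[perm]), q[perm])
})

test_that("Q1-vs-Q4 chi-squared matches the textbook oracle", {
  # [[10,40],[30,20]]: expected [[20,30],[20,30]] -> chi2 = 16.667
  qs <- factor(rep(c("Q1", "Q4"), each = 50), levels = paste0("Q", 1:4))
  feat <- c(rep(1, 10), rep(0, 40), rep(1, 30), rep(0, 20))
  res <- q1_vs_q4_test(feat, qs, "binary")
  expect_equal(res$statistic, 50 / 3, tolerance = 1e-10)
  # random 2x2 tables against sum((O-E)^2/E)
  set.seed(13)
  for (i in 1:20) {
    n1 <- sample(10:60, 1); n4 <- sample(10:60, 1)
    f <- c(rbinom(n1, 1, 0.4), rbinom(n4, 1, 0.6))
    qf <- factor(rep(c("Q1", "Q4"), c(n1, n4)), levels = paste0("Q", 1:4))
    if (length(unique(f[1:n1])) < 2 && length(unique(f)) < 2) next
    O <- rbind(c(sum(f[1:n1]), n1 - sum(f[1:n1])),
               c(sum(f[-(1:n1)]), n4 - sum(f[-(1:n1)])))
    if (any(colSums(O) == 0)) next
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    expect_equal(q1_vs_q4_test(f, qf, "binary")$statistic,
                 sum((O - E)^2 / E), tolerance = 1e-10)
  }
})

test_that("Q1-vs-Q4 continuous contrast is the Student t test", {
  set.seed(17)
  v <- c(rnorm(20), rnorm(20, 1))
  qs <- factor(rep(c("Q1", "Q4"), each = 20), levels = paste0("Q", 1:4))
  res <- q1_vs_q4_test(v, qs, "continuous")
  ref <- t.test(v[1:20], v[21:40], var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  # identical group proportions give statistic 0
  same <- c(rep(c(1, 0), 10), rep(c(1, 0), 10))
  expect_equal(q1_vs_q4_test(same, qs, "binary")$statistic, 0)
})

test_that("trend test recovers an exact ordinal slope", {
  qs <- factor(rep(paste0("Q", 1:4), each = 5), levels = paste0("Q", 1:4))
  v <- rep(1:4, each = 5)   # quartile means exactly 1..4, no within-group var
  res <- suppressWarnings(trend_test(v, qs))
  expect_equal(res$slope, 1, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-12)
  const <- suppressWarnings(trend_test(rep(2, 20), qs))
  expect_equal(const$slope, 0)
  expect_error(trend_test(1:5, factor(rep("Q1", 5),
                                      levels = paste0("Q", 1:4))),
               "distinct quartiles")
})

test_that("ER gene-group score is the unweighted four-gene mean", {
  m <- rbind(ESR1 = c(8, 7), PGR = c(9, 7), BCL2 = c(10, 7), SCUBE2 = c(9, 7),
             OTHER = c(99, 99))
  colnames(m) <- c("a", "b")
  s <- er_gene_score(m)
  expect_equal(unname(s["a"]), 9)
  expect_equal(unname(s["b"]), 7)
  expect_error(er_gene_score(m[-1, , drop = FALSE]), "ESR1")
})

test_that("MATH score follows the ratio convention", {
  expect_equal(math_score(c(0.2, 0.3, 0.4)), 0.1 / 0.3)
  expect_equal(math_score(rep(0.25, 5)), 0)
  expect_error(math_score(c(0.1, 0.2)), "at least 3")
  expect_error(math_score(c(0, 0, 0)), "undefined")
})

test_that("Kaplan-Meier estimates match the product-limit by hand", {
  res <- km_logrank(c(1, 2, 3), c(1, 1, 1), rep("g", 3))
  expect_equal(res$curves$survival, c(2 / 3, 1 / 3, 0))
  expect_true(is.na(res$p_value))
  # identical groups: log-rank statistic 0, p = 1
  t2 <- rep(c(1, 2, 3), 2); e2 <- rep(1, 6)
  g2 <- rep(c("a", "b"), each = 3)
  res2 <- km_logrank(t2, e2, g2)
  expect_equal(res2$statistic, 0, tolerance = 1e-12)
  expect_equal(res2$p_value, 1)
  expect_error(km_logrank(c(1, 2), c(0, 0), c("a", "b")), "no events")
  expect_error(km_logrank(c(0, 2), c(1, 1), c("a", "b")), "positive")
})

test_that("product-limit equals an enumerated oracle on small datasets", {
  # all event patterns on <= 6 uncensored observations
  km_oracle <- function(times) {
    tt <- sort(unique(times))
    n <- length(times)
    s <- numeric(length(tt)); cur <- 1
    for (i in seq_along(tt)) {
      d <- sum(times == tt[i])
      at_risk <- sum(times >= tt[i])
      cur <- cur * (1 - d / at_risk)
      s[i] <- cur
    }
    s
  }
  set.seed(19)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    times <- sample(1:4, n, replace = TRUE)
    res <- km_logrank(times, rep(1, n), rep("g", n))
    expect_equal(res$curves$survival, km_oracle(times), tolerance = 1e-12)
  }
})

test_that("Cox stratification censors and landmarks at 36 months", {
  set.seed(23)
  n <- 400
  g <- factor(rep(c("pure", "admixed"), each = n / 2),
              levels = c("pure", "admixed"))
  t0 <- c(rexp(n / 2, 0.01), rexp(n / 2, 0.02))
  ev <- rep(1L, n)
  full <- cox_hr(t0, ev, g, stratum = "entire")
  expect_gt(full$hazard_ratio, 1)
  expect_true(full$ci_low <= full$hazard_ratio &&
                full$hazard_ratio <= full$ci_high)
  early <- cox_hr(t0, ev, g, stratum = "0-3y")
  expect_equal(early$n, n)
  expect_equal(early$n_events, sum(t0 <= 36))
  late <- cox_hr(t0, ev, g, stratum = ">3y")
  expect_equal(late$n, sum(t0 > 36))
  expect_error(cox_hr(c(1, 2), c(0, 0), factor(c("a", "b"))), "no events")
})

test_that("a planted hazard ratio of 2 is recovered and the null is clean", {
  set.seed(29)
  n <- 500
  g <- factor(rep(c("pure", "admixed"), each = n / 2),
              levels = c("pure", "admixed"))
  lam <- ifelse(g == "admixed", 0.02, 0.01)
  res <- cox_hr(rexp(n, lam), rep(1, n), g)
  expect_gte(res$hazard_ratio, 1.6)
  expect_lte(res$hazard_ratio, 2.5)
  null <- cox_hr(rexp(n, 0.01), rep(1, n), g)
  expect_gte(null$ci_high, 1)
  expect_lte(null$ci_low, 1)
  expect_gte(null$hazard_ratio, 0.8)
  expect_lte(null$hazard_ratio, 1.25)
})

test_that("log-HR bias shrinks with sample size", {
  bias_at <- function(n, seed) {
    set.seed(seed)
    g <- factor(rep(c("pure", "admixed"), each = n / 2),
                levels = c("pure", "admixed"))
    lam <- ifelse(g == "admixed", 0.02, 0.01)
    reps <- vapply(1:20, function(i) {
      log(cox_hr(rexp(n, lam), rep(1, n), g)$hazard_ratio)
    }, numeric(1))
    abs(mean(reps) - log(2))
  }
  b <- c(bias_at(100, 1), bias_at(500, 2), bias_at(2000, 3))
  expect_lt(b[3], 0.05)
  expect_lt(b[3], b[1] + 0.02)
})
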