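test_that("condition_summary aggregates trial means per subject and condition", {
  trials <- data.frame(
    subject = rep(1:3, each = 4),
    condition = rep(c("P", "S", "R", "U"), 3),
    mean_distance = as.numeric(1:12))
  m <- condition_summary(trials)
  expect_identical(dim(m), c(3L, 4L))
  expect_equal(m["1", "P"], 1)
  expect_equal(m["3", "U"], 12)

  # two equal trials per cell: same as one
  trials2 <- rbind(trials, trials)
  expect_equal(unclass(condition_summary(trials2)), unclass(m))

  # random trial counts against brute-force means
  set.seed(13)
  long <- do.call(rbind, lapply(1:4, function(s) {
    do.call(rbind, lapply(c("P", "S", "R", "U"), function(cnd) {
      data.frame(subject = s, condition = cnd,
                 mean_distance = runif(sample(1:4, 1), 5, 40))
    }))
  }))
  m2 <- condition_summary(long)
  for (s in 1:4) for (cnd in c("P", "S", "R", "U")) {
    expect_equal(m2[as.character(s), cnd],
                 mean(long$mean_distance[long$subject == s &
                                           long$condition == cnd]))
  }

  expect_error(condition_summary(trials[-2, ]), "no trial in condition")
})

test_that("rm_anova matches hand cases and an independent aov/eigen oracle", {
  # equal condition means: zero effect SS, F = 0
  r <- rm_anova(matrix(c(1, 2, 2, 1), 2, 2))
  expect_equal(r$ss[["conditions"]], 0)
  expect_equal(r$F, 0)
  # two conditions: sphericity is vacuous
  expect_equal(r$epsilon_gg, 1)

  set.seed(2024)
  for (rep in 1:3) {
    m <- matrix(rnorm(80, mean = 20, sd = 4), 20, 4) +
      outer(rnorm(20, 0, 3), rep(1, 4)) + outer(rep(1, 20), c(0, 1, 2, 5))
    colnames(m) <- c("P", "S", "R", "U")
    r <- rm_anova(m)

    # oracle 1: stats::aov with a subject error stratum
    df <- data.frame(y = as.vector(m),
                     subj = factor(rep(1:20, 4)),
                     cond = factor(rep(1:4, each = 20)))
    a <- summary(stats::aov(y ~ cond + Error(subj/cond), data = df))
    tab <- a[["Error: subj:cond"]][[1]]
    expect_equal(r$F, tab["cond", "F value"], tolerance = 1e-8)
    expect_equal(r$df1_uncorrected, tab["cond", "Df"])

    # oracle 2: epsilon from the eigenvalues of the double-centered
    # covariance matrix
    S <- cov(m)
    k <- ncol(m)
    C <- diag(k) - matrix(1 / k, k, k)
    lam <- eigen(C %*% S %*% C, symmetric = TRUE, only.values = TRUE)$values
    eps_oracle <- sum(lam)^2 / ((k - 1) * sum(lam^2))
    expect_equal(r$epsilon_gg, eps_oracle, tolerance = 1e-8)

    # oracle 3: p from the F distribution at the corrected df
    expect_equal(r$p, pf(r$F, (k - 1) * eps_oracle, (k - 1) * 19 * eps_oracle,
                         lower.tail = FALSE), tolerance = 1e-8)
  }

  expect_error(rm_anova(matrix(5, 4, 3)), "constant matrix")
})

test_that("sum-of-squares decomposition conserves and epsilon stays in range", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:25, 1); k <- sample(2:6, 1)
    m <- matrix(rnorm(n * k), n, k)
    r <- rm_anova(m)
    expect_equal(r$ss[["subjects"]] + r$ss[["conditions"]] + r$ss[["error"]],
                 r$ss[["total"]], tolerance = 1e-9)
    expect_gte(r$epsilon_gg, 1 / (k - 1) - 1e-12)
    expect_lte(r$epsilon_gg, 1)
  }
})

test_that("paired comparisons match hand-computed d and stats::t.test", {
  m <- cbind(P = c(1, 2, 3, 4), S = c(1, 2, 3, 4))
  r <- paired_comparisons(m, list(c("P", "S")))
  expect_equal(r$t, 0)
  expect_equal(r$d, 0)
  expect_equal(r$p_raw, 1)

  # differences (1, 1, 3, 3): d = 2 / sd = sqrt(3)
  m2 <- cbind(A = c(2, 3, 6, 8), B = c(1, 2, 3, 5))
  r2 <- paired_comparisons(m2, list(c("A", "B")))
  expect_equal(r2$d, 2 / sd(c(1, 1, 3, 3)))
  expect_equal(r2$d, sqrt(3), tolerance = 1e-12)
  tt <- t.test(m2[, "A"], m2[, "B"], paired = TRUE)
  expect_equal(r2$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r2$p_raw, tt$p.value, tolerance = 1e-12)

  # Bonferroni multiplier equals the number of requested pairs
  set.seed(8)
  m4 <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, c("P", "S", "R", "U")))
  r4 <- paired_comparisons(m4)
  expect_identical(nrow(r4), 6L)
  expect_equal(r4$p_bonferroni, pmin(1, 6 * r4$p_raw))

  # zero difference variance with nonzero mean is flagged undefined
  m5 <- cbind(A = c(2, 3, 4), B = c(1, 2, 3))
  r5 <- paired_comparisons(m5, list(c("A", "B")))
  expect_true(r5$undefined)
  expect_identical(r5$t, Inf)
})

test_that("matrix CSV round trip preserves values", {
  m <- matrix(runif(12, 10, 40), 3, 4,
              dimnames = list(c("s1", "s2", "s3"), c("P", "S", "R", "U")))
  class(m) <- c("condition_matrix", class(m))
  path <- withr::local_tempfile(fileext = ".csv")
  write_condition_matrix(m, path)
  m2 <- read_condition_matrix(path)
  expect_equal(unclass(m2), unclass(m), tolerance = 1e-12)
})
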