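test_that("Friedman test matches the hand-ranked chi-square", {
  m <- matrix(c(1, 2, 3,
                2, 4, 6,
                1.5, 2.5, 9), nrow = 3, byrow = TRUE)  # increasing rows
  res <- friedman_rank_test(m)
  # every subject ranks the days 1 < 2 < 3: rank sums 3, 6, 9
  # Xr2 = 12 / (n k (k + 1)) * sum(R^2) - 3 n (k + 1) = 6
  expect_equal(unname(res$statistic["Xr2"]), 6, tolerance = 1e-9)
  expect_equal(res$df, 2)

  same <- matrix(rep(c(4, 4, 4), 3), nrow = 3, byrow = TRUE)
  res2 <- friedman_rank_test(same)
  expect_equal(unname(res2$statistic["Xr2"]), 0)
  expect_equal(res2$p, 1)

  m[2, 3] <- NA
  expect_error(friedman_rank_test(m), "missing cells")
})

test_that("Friedman statistic is invariant to relabelling days", {
  set.seed(5)
  m <- matrix(rnorm(24), 6, 4)
  perm <- c(3, 1, 4, 2)
  expect_equal(friedman_rank_test(m)$statistic,
               friedman_rank_test(m[, perm])$statistic)
})

test_that("paired Wilcoxon flags degenerate input and reports its method", {
  a <- c(3, 5, 7, 9)
  expect_error(wilcoxon_paired(a, a), "degenerate")
  res <- wilcoxon_paired(c(1, 2, 3, 4, 6), c(2, 4, 7, 9, 12))
  expect_identical(res$method_detail, "exact")
  expect_true(res$p >= 0 && res$p <= 1)
})

test_that("Mann-Whitney U matches exact enumeration on the toy sample", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(unname(res$statistic["U"]), 0)
  # oracle: enumerate all choose(4, 2) = 6 label arrangements of the
  # pooled sample and count those with U as or more extreme
  pool <- c(1, 2, 3, 4)
  us <- apply(utils::combn(4, 2), 2, function(idx) {
    sum(outer(pool[idx], pool[-idx], ">")) })
  p_exact <- 2 * mean(us <= 0)
  expect_equal(res$p, p_exact, tolerance = 1e-9)   # = 1/3
})

test_that("Mann-Whitney U statistics of the two orderings are complementary", {
  set.seed(7)
  a <- rnorm(8); b <- rnorm(11) + 0.5
  ua <- unname(mann_whitney(a, b)$statistic["U"])
  ub <- unname(mann_whitney(b, a)$statistic["U"])
  expect_equal(ua + ub, length(a) * length(b))
})

test_that("randomised-block ANOVA matches a brute-force decomposition", {
  m <- matrix(c(3, 5, 4,
                6, 9, 8), nrow = 2, byrow = TRUE)   # 2 blocks x 3 days
  res <- blocked_anova_tukey(m)
  # oracle: direct sums of squares
  gm <- mean(m)
  ss_day <- nrow(m) * sum((colMeans(m) - gm)^2)
  ss_block <- ncol(m) * sum((rowMeans(m) - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_err <- ss_tot - ss_day - ss_block
  f_oracle <- (ss_day / (ncol(m) - 1)) /
    (ss_err / ((nrow(m) - 1) * (ncol(m) - 1)))
  expect_equal(unname(res$statistic["F"]), f_oracle, tolerance = 1e-9)
  expect_equal(res$df, c(2, 2))
  expect_equal(nrow(res$tukey), 3)

  # constant table: F = 0 by convention
  expect_equal(unname(blocked_anova_tukey(matrix(5, 3, 4))$statistic["F"]), 0)

  # adding a per-block constant cannot change the day effect
  shifted <- m + c(100, -40)
  expect_equal(blocked_anova_tukey(shifted)$statistic, res$statistic,
               tolerance = 1e-9)

  m[2, 1] <- NA
  expect_error(blocked_anova_tukey(m), "incomplete blocks")
})

test_that("repeated-measures ANOVA validates balance and collapses correctly", {
  set.seed(12)
  d <- expand.grid(subject = paste0("s", 1:5), day = 1:3, freq = c(7, 8))
  d$rp <- rnorm(nrow(d))
  res <- rm_anova(d, dv = "rp", subject = "subject",
                  within = c("day", "freq"))
  expect_true(all(c("day", "freq", "day:freq") %in% res$effect))
  expect_true(all(res$p >= 0 & res$p <= 1))

  # one-level second factor reduces to the one-way RM-ANOVA
  d7 <- d[d$freq == 7, ]
  two <- rm_anova(d7, dv = "rp", subject = "subject",
                  within = c("day", "freq"))
  one <- rm_anova(d7, dv = "rp", subject = "subject", within = "day")
  expect_equal(two$F[two$effect == "day"], one$F[one$effect == "day"],
               tolerance = 1e-9)

  # missing cell is a design error naming the cell
  expect_error(rm_anova(d[-1, ], dv = "rp", subject = "subject",
                        within = c("day", "freq")), "design error")

  # day-subset option drops the other days
  sub <- rm_anova(d, dv = "rp", subject = "subject",
                  within = c("day", "freq"), days = c(1, 3))
  expect_equal(sub$df1[sub$effect == "day"], 1)
})

test_that("Greenhouse-Geisser epsilon stays in its admissible range", {
  set.seed(3)
  d <- expand.grid(subject = paste0("s", 1:8), day = 1:4, freq = c(7, 8, 9))
  d$rp <- rnorm(nrow(d)) + as.numeric(d$day) * (d$freq - 8)
  res <- rm_anova(d, dv = "rp", subject = "subject",
                  within = c("day", "freq"), gg = TRUE)
  i <- res$effect == "day:freq"
  expect_true(res$eps_gg[i] >= 1 / res$df1[1] && res$eps_gg[i] <= 1)
  expect_true(res$p_gg[i] >= res$p[i] - 1e-12)   # correction never anti-conservative here
})

test_that("paired t with Bonferroni matches hand computation and flags zeros", {
  cmp <- list(
    toy = list(a = c(1, 2, 3), b = c(2, 4, 3)),
    shift = list(a = c(3, 5, 7, 9, 11), b = c(2, 4, 6, 8, 10)))
  res <- paired_t_bonferroni(cmp)
  d <- c(1, 2, 3) - c(2, 4, 3)
  t_oracle <- mean(d) / (stats::sd(d) / sqrt(3))
  expect_equal(res$t[1], t_oracle, tolerance = 1e-9)
  expect_equal(res$df[1], 2)
  expect_equal(res$p_bonferroni[1], min(1, res$p[1] * 2))
  # constant difference: degenerate, flagged, not an infinite t
  expect_true(res$degenerate[2])
  expect_true(is.na(res$t[2]))

  # m = 1 reduces to the plain paired t-test
  single <- paired_t_bonferroni(cmp["toy"])
  tt <- stats::t.test(cmp$toy$a, cmp$toy$b, paired = TRUE)
  expect_equal(single$p[1], tt$p.value, tolerance = 1e-12)
  expect_equal(single$p_bonferroni[1], single$p[1])
})

test_that("group shifts move the test statistics monotonically", {
  a <- c(1, 2, 3, 4, 5)
  e <- c(-0.3, 0.1, 0.4, -0.2, 0)        # zero-mean within-pair noise
  deltas <- c(0.5, 1, 2, 4)
  ts <- vapply(deltas, function(dl) {
    abs(paired_t_bonferroni(list(x = list(a = a + dl + e, b = a)))$t[1])
  }, 0)
  expect_true(all(diff(ts) >= 0))
  us <- vapply(deltas, function(dl) {
    unname(mann_whitney(a + dl, a)$statistic["U"])
  }, 0)
  expect_true(all(diff(us) >= 0))
})
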