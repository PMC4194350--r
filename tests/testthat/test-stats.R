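# Group statistics: descriptives, Jarque-Bera, two-sample tests,
# Holm-Bonferroni, group comparison plumbing.

test_that("descriptive statistics match the textbook values", {
  d <- descriptiveStats(c(1, 2, 3, 4, 5))
  expect_equal(d$mean, 3)
  expect_equal(d$sd, sqrt(2.5))
  expect_equal(d$median, 3)
  expect_equal(d$min, 1)
  expect_equal(d$max, 5)
  d1 <- descriptiveStats(7)
  expect_equal(d1$mean, 7)
  expect_true(is.na(d1$sd))
  expect_equal(d1$median, 7)
  expect_equal(descriptiveStats(c(2, 2, 2))$sd, 0)
  expect_equal(descriptiveStats(c(1, 2, 3, 4))$median, 2.5)
  expect_error(descriptiveStats(numeric(0)), "at least one")
})

test_that("Jarque-Bera uses biased moments and the chi-squared(2) law", {
  jb <- jarqueBera(c(1, 2, 3, 4, 5))
  # m2 = 2, m4 = 6.8 -> S = 0, K = 1.7, JB = 5/6 * (1.3^2 / 4)
  expect_equal(jb$skewness, 0)
  expect_equal(jb$kurtosis, 1.7)
  expect_equal(jb$statistic, 5 / 6 * (1.3^2 / 4))
  expect_equal(jb$statistic, 0.3520833, tolerance = 1e-6)
  expect_equal(jb$p.value, pchisq(jb$statistic, 2, lower.tail = FALSE))
  expect_true(jb$small_sample)
  # symmetric samples have zero skewness term
  expect_equal(jarqueBera(c(-3, -1, 0, 1, 3))$skewness, 0)
  # degenerate inputs flagged not-computable
  expect_true(is.na(jarqueBera(c(1, 2, 3))$statistic))
  expect_true(is.na(jarqueBera(rep(4, 10))$statistic))
  expect_false(jarqueBera(rnorm(50))$small_sample)
})

test_that("Jarque-Bera keeps its size on large normal samples", {
  set.seed(1234)
  ok <- vapply(1:200, function(i) jarqueBera(rnorm(5000))$p.value > 0.01,
               logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("pooled Student's t matches hand-computed values", {
  ht <- studentT(c(1, 2, 3), c(2, 3, 4))
  expect_equal(ht$statistic, -sqrt(3) / sqrt(2), tolerance = 1e-12)
  expect_equal(ht$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(ht$df, 4)
  expect_equal(ht$p.value, 2 * pt(-sqrt(1.5), 4))
  expect_equal(ht$p.value, 0.2878641, tolerance = 1e-6)
  # identical groups
  same <- studentT(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # antisymmetry
  a <- rnorm(8); b <- rnorm(8) + 1
  expect_equal(studentT(a, b)$statistic, -studentT(b, a)$statistic)
  expect_equal(studentT(a, b)$p.value, studentT(b, a)$p.value)
  # degenerate variance conventions
  expect_equal(studentT(c(2, 2), c(2, 2))$p.value, 1)
  degen <- studentT(c(2, 2), c(3, 3))
  expect_true(is.infinite(degen$statistic))
  expect_equal(degen$p.value, 0)
  # Welch option reduces to t.test(var.equal = FALSE)
  w <- studentT(a, b, welch = TRUE)
  expect_equal(w$p.value, t.test(a, b)$p.value)
})

test_that("Mann-Whitney U convention and exact p", {
  mw <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic, 0)
  expect_true(mw$exact)
  expect_equal(mw$p.value, 0.1)   # 2 / choose(6, 3)
  # pairing identity and tie-half convention
  a <- c(1.5, 9, 4); b <- c(2, 8, 7, 3)
  expect_equal(mannWhitneyU(a, b)$statistic + mannWhitneyU(b, a)$statistic,
               length(a) * length(b))
  same <- c(3, 1, 4, 1)
  expect_equal(mannWhitneyU(same, same)$statistic, length(same)^2 / 2)
})

test_that("Mann-Whitney exact p agrees with full enumeration, n <= 5", {
  set.seed(99)
  for (na in 1:5) for (nb in 1:5) {
    vals <- sample(seq_len(50), na + nb)   # distinct -> no ties
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    expect_equal(mannWhitneyU(a, b)$p.value, enumMannWhitneyP(a, b),
                 tolerance = 1e-12,
                 label = sprintf("n_a=%d n_b=%d", na, nb))
  }
})

test_that("Holm-Bonferroni steps down, caps and preserves order", {
  expect_equal(holmBonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holmBonferroni(0.2), 0.2)
  expect_equal(holmBonferroni(c(0.5, 0.9)), c(1, 1))
  set.seed(3)
  p <- runif(20)
  adj <- holmBonferroni(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= 0))  # weak rank preservation
  expect_error(holmBonferroni(c(0.1, 1.2)), "\\[0,1\\]")
})

test_that("t-test keeps its nominal size under the null at n = 8", {
  set.seed(2024)
  reps <- 1000
  rej <- vapply(seq_len(reps), function(i)
    studentT(rnorm(8), rnorm(8))$p.value < 0.05, logical(1))
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})

test_that("group comparison assembles results and applies the correction", {
  mkSumm <- function(pid, v1, v2) data.frame(
    plate_id = pid, subset = "all", n_spots_per_fly = v1, mean_l = v2,
    stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(1:8, function(i)
    mkSumm(paste0("p", i), c(1, 2, 3, 4, 11, 12, 13, 14)[i],
           c(5, 6, 7, 8, 6, 7, 8, 9)[i] / 20)))
  groups <- list(ctrl = paste0("p", 1:4), treat = paste0("p", 5:8))
  res <- compareGroups(summ, groups, c("n_spots_per_fly", "mean_l"),
                       test = "student_t", correct = TRUE)
  expect_equal(nrow(res), 2)
  expect_equal(res$adjusted_p, holmBonferroni(res$raw_p))
  expect_true(all(res$adjusted_p >= res$raw_p))
  expect_true(all(res$small_sample))
  # identical groups give p = 1 both raw and adjusted
  summEq <- rbind(mkSumm(paste0("a", 1:3), c(1, 2, 3), 0.5),
                  mkSumm(paste0("b", 1:3), c(1, 2, 3), 0.5))
  resEq <- compareGroups(summEq, list(g1 = paste0("a", 1:3),
                                      g2 = paste0("b", 1:3)),
                         "n_spots_per_fly")
  expect_equal(resEq$raw_p, 1)
  expect_equal(resEq$adjusted_p, 1)
  # correct = FALSE passes raw p through
  resU <- compareGroups(summ, groups, c("n_spots_per_fly", "mean_l"),
                        correct = FALSE)
  expect_equal(resU$adjusted_p, resU$raw_p)
  # Mann-Whitney route
  resMW <- compareGroups(summ, groups, "n_spots_per_fly",
                         test = "mann_whitney")
  expect_equal(resMW$statistic, 0)   # complete separation, ctrl below treat
  # errors
  expect_error(compareGroups(summ, groups, "nope"), "unknown variable")
  expect_error(compareGroups(summ, list(g = "missing_plate", h = "p1"),
                             "mean_l"),
               "unknown plate")
  expect_error(compareGroups(summ, list(g = "p1"), "mean_l"),
               "two groups")
  expect_error(compareGroups(summ, list(a = "p1", b = "p1"), "mean_l"),
               "disjoint")
})

test_that("group descriptives summarise each group and variable", {
  summ <- data.frame(plate_id = paste0("p", 1:6), subset = "all",
                     total_iod_per_fly = c(1, 2, 3, 10, 20, 30))
  groups <- list(lo = paste0("p", 1:3), hi = paste0("p", 4:6))
  gd <- groupDescriptives(summ, groups, "total_iod_per_fly")
  expect_equal(nrow(gd), 2)
  expect_equal(gd$mean[gd$group == "lo"], 2)
  expect_equal(gd$median[gd$group == "hi"], 20)
  expect_equal(gd$sd[gd$group == "lo"], 1)
})
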