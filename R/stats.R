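# Group-level statistics: descriptives, Jarque-Bera normality guidance,
# two-sample tests (Student's t / Mann-Whitney U) and Holm-Bonferroni
# familywise correction.

#' Descriptive statistics of a sample
#'
#' @param values numeric vector, length >= 1 (NAs removed).
#' @return A list with `n`, `mean`, `sd` (sample standard deviation,
#'   `NA` for n = 1), `median`, `min`, `max`.
#' @examples
#' descriptiveStats(c(1, 2, 3, 4, 5))  # mean 3, sd sqrt(2.5)
#' @export
descriptiveStats <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1L) stop("need at least one value")
  list(n = n, mean = mean(values),
       sd = if (n > 1L) sd(values) else NA_real_,
       median = median(values), min = min(values), max = max(values))
}

#' Jarque-Bera normality test
#'
#' `JB = n/6 * (S^2 + (K - 3)^2 / 4)` with S the sample skewness and K the
#' sample kurtosis, both from biased central moments; the p-value comes
#' from the asymptotic chi-squared distribution with 2 degrees of freedom.
#' The statistic only guides the choice between parametric and
#' non-parametric group tests — it never switches the test automatically.
#' For n < 30 the asymptotic law is unreliable and `small_sample` is set;
#' care should be taken when inferring normality (or its lack) from small
#' plate groups.
#'
#' @param values numeric vector, n >= 4, non-degenerate.
#' @return A list with `statistic`, `p.value`, `skewness`, `kurtosis`,
#'   `n` and `small_sample`; `statistic` and `p.value` are `NA` when the
#'   test is not computable (n < 4 or zero variance).
#' @examples
#' jarqueBera(c(1, 2, 3, 4, 5))  # JB = 5/6 * (1.69/4) ~ 0.352
#' @export
jarqueBera <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  notComputable <- function(why)
    list(statistic = NA_real_, p.value = NA_real_, skewness = NA_real_,
         kurtosis = NA_real_, n = n, small_sample = n < 30L, reason = why)
  if (n < 4L) return(notComputable("n < 4"))
  m <- values - mean(values)
  m2 <- mean(m^2)
  if (m2 == 0) return(notComputable("zero variance"))
  S <- mean(m^3) / m2^1.5
  K <- mean(m^4) / m2^2
  jb <- n / 6 * (S^2 + (K - 3)^2 / 4)
  list(statistic = jb, p.value = pchisq(jb, df = 2, lower.tail = FALSE),
       skewness = S, kurtosis = K, n = n, small_sample = n < 30L,
       reason = NA_character_)
}

#' Two-sample Student's t-test
#'
#' Pooled-variance Student's t by default (`df = n_a + n_b - 2`), with
#' Welch's unequal-variance form as an option. Degenerate inputs are
#' resolved explicitly: two constant samples with equal means give
#' `t = 0, p = 1`; zero pooled variance with unequal means gives an
#' infinite statistic with `p = 0`.
#'
#' @param a,b numeric vectors, each of length >= 2 (NAs removed).
#' @param welch use Welch's correction instead of the pooled form.
#' @return A list with `statistic`, `df`, `p.value`, `method`.
#' @examples
#' studentT(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df = 4
#' @export
studentT <- function(a, b, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need at least 2 values")
  method <- if (welch) "welch_t" else "student_t"
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, df = length(a) + length(b) - 2L,
                  p.value = 1, method = method))
    return(list(statistic = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2L, p.value = 0,
                method = method))
  }
  ht <- t.test(a, b, var.equal = !welch)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, method = method)
}

#' Mann-Whitney U test
#'
#' `U` counts the pairs `(a_i, b_j)` won by group `a` (i.e. `a_i > b_j`),
#' ties counting one half, so `U_a + U_b = n_a * n_b`. The two-sided
#' p-value is exact (full enumeration of rank assignments) when
#' `n_a + n_b <= 16` and there are no ties — cheap at the plate-group sizes
#' typical of excretion assays (6-8 replicates) — and otherwise uses the
#' normal approximation with tie and continuity corrections.
#'
#' @param a,b numeric vectors, each of length >= 1 (NAs removed).
#' @return A list with `statistic` (U for group `a`), `p.value` and
#'   `exact` (logical).
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitneyU <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 1L || length(b) < 1L)
    stop("both groups need at least 1 value")
  gt <- outer(a, b, ">")
  eq <- outer(a, b, "==")
  U <- sum(gt) + sum(eq) / 2
  ties <- any(eq) || anyDuplicated(a) > 0L || anyDuplicated(b) > 0L
  exact <- (length(a) + length(b) <= 16L) && !ties
  p <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  list(statistic = U, p.value = p, exact = exact)
}

#' Holm-Bonferroni step-down correction
#'
#' Controls the familywise error rate across a family of comparisons:
#' the i-th smallest p-value is multiplied by (m - i + 1), the sequence is
#' made monotone non-decreasing and capped at 1. Less conservative than
#' plain Bonferroni, but still conservative — when trying to demonstrate a
#' lack of effect the correction should be skipped (see
#' [compareGroups()]'s `correct` argument).
#'
#' @param pvals raw p-values in \[0,1\].
#' @return Adjusted p-values in the original order.
#' @examples
#' holmBonferroni(c(0.01, 0.04, 0.03))  # 0.03, 0.06, 0.06
#' @export
holmBonferroni <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0,1]")
  p.adjust(pvals, method = "holm")
}

#' Compare plate groups variable by variable
#'
#' Runs one two-sample test per (variable, group pair) on plate-level
#' summary values, with per-group Jarque-Bera normality guidance and
#' optional Holm-Bonferroni correction across the whole requested family.
#' Test selection is manual: the normality p-values are displayed guidance,
#' never an automatic switch.
#'
#' @param summaries stacked plate summary table (rows from
#'   [summarizePlate()] over several plates).
#' @param groups named list mapping group names to plate_id vectors;
#'   groups must be disjoint and resolve to rows of `summaries`.
#' @param variables summary column names to compare (e.g.
#'   `"n_spots_per_fly"`, `"total_iod_per_fly"`, `"mean_l"`).
#' @param subset which summary subset to draw values from: `"all"`
#'   (default), `"rod"` or `"non_rod"`.
#' @param test `"student_t"` (default) or `"mann_whitney"`.
#' @param correct apply Holm-Bonferroni across all comparisons of this
#'   call (default TRUE). Skip it when trying to show a lack of effect,
#'   where its conservatism inflates Type II errors.
#' @param welch for `"student_t"`, use Welch's form.
#' @return A `data.frame` with one row per (variable, group pair):
#'   `variable`, `group_a`, `group_b`, `n_a`, `n_b`, `test`, `statistic`,
#'   `df`, `raw_p`, `adjusted_p`, `normality_p_a`, `normality_p_b`,
#'   `small_sample`.
#' @export
compareGroups <- function(summaries, groups, variables, subset = "all",
                          test = c("student_t", "mann_whitney"),
                          correct = TRUE, welch = FALSE) {
  test <- match.arg(test)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named list")
  if (length(groups) < 2L)
    stop("need at least two groups to compare")
  ids <- unlist(groups)
  if (anyDuplicated(ids)) stop("groups must be disjoint")
  s <- summaries[summaries$subset == subset, , drop = FALSE]
  missing <- setdiff(ids, s$plate_id)
  if (length(missing))
    stop("unknown plate_id(s): ", paste(missing, collapse = ", "))
  bad <- setdiff(variables, names(s))
  if (length(bad))
    stop("unknown variable(s): ", paste(bad, collapse = ", "))
  pairs <- combn(names(groups), 2L, simplify = FALSE)
  rows <- list()
  nSkipped <- 0L
  for (v in variables) {
    vals <- lapply(groups, function(g) {
      x <- s[[v]][match(g, s$plate_id)]
      nSkipped <<- nSkipped + sum(is.na(x))
      x[!is.na(x)]
    })
    for (pr in pairs) {
      va <- vals[[pr[1L]]]; vb <- vals[[pr[2L]]]
      if (test == "student_t") {
        ht <- studentT(va, vb, welch = welch)
        stat <- ht$statistic; df <- ht$df; p <- ht$p.value
      } else {
        ht <- mannWhitneyU(va, vb)
        stat <- ht$statistic; df <- NA_real_; p <- ht$p.value
      }
      jba <- jarqueBera(va); jbb <- jarqueBera(vb)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, group_a = pr[1L], group_b = pr[2L],
        n_a = length(va), n_b = length(vb),
        test = ht$method %||% test, statistic = stat, df = df, raw_p = p,
        adjusted_p = NA_real_,
        normality_p_a = jba$p.value, normality_p_b = jbb$p.value,
        small_sample = isTRUE(jba$small_sample) || isTRUE(jbb$small_sample),
        stringsAsFactors = FALSE)
    }
  }
  if (nSkipped > 0L)
    message(nSkipped, " missing plate value(s) skipped")
  out <- do.call(rbind, rows)
  out$adjusted_p <- if (correct) holmBonferroni(out$raw_p) else out$raw_p
  rownames(out) <- NULL
  out
}

#' Descriptive statistics per group
#'
#' The descriptive companion of [compareGroups()]: mean, standard
#' deviation, median, minimum and maximum of each plate-level variable
#' within each group.
#'
#' @inheritParams compareGroups
#' @return A `data.frame` with one row per (group, variable).
#' @export
groupDescriptives <- function(summaries, groups, variables, subset = "all") {
  s <- summaries[summaries$subset == subset, , drop = FALSE]
  rows <- list()
  for (g in names(groups)) {
    for (v in variables) {
      x <- s[[v]][match(groups[[g]], s$plate_id)]
      x <- x[!is.na(x)]
      d <- descriptiveStats(x)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, variable = v, n = d$n, mean = d$mean, sd = d$sd,
        median = d$median, min = d$min, max = d$max,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
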