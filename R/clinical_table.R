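#' Medication response label from VAS change
#'
#' Patients whose VAS reduction after one week of treatment is less than
#' three are labeled medication-resistant (MRP); a reduction of three or more
#' is medication-sensitive (MSP).
#'
#' @param pre_vas,post_vas VAS scores in `[0, 10]` (vectorized).
#' @return Character vector of `"MRP"` / `"MSP"`.
#' @export
label_response <- function(pre_vas, post_vas) {
  reduction <- delta_vas(pre_vas, post_vas)
  ifelse(reduction < 3, "MRP", "MSP")
}

#' Group summary (n, mean, sd)
#'
#' @param n Group size (>= 2).
#' @param mean Sample mean.
#' @param sd Sample standard deviation (>= 0).
#' @return A `group_summary` object.
#' @export
group_summary <- function(n, mean, sd) {
  if (n < 2) stop_invalid("group size must be >= 2")
  if (sd < 0) stop_invalid("sd must be non-negative")
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

#' Two-sample t-test from group summaries
#'
#' Welch (default; unequal variances, Satterthwaite df) or Student
#' (pooled-variance) two-sample t-test computed from (n, mean, sd) summaries.
#'
#' @param a,b [group_summary()] objects (or lists with n/mean/sd).
#' @param variant `"welch"` or `"student"`.
#' @return List with `t`, `df`, `p` (two-tailed).
#' @export
two_sample_t <- function(a, b, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (a$sd == 0 && b$sd == 0) {
    stop_invalid("both group sds are zero; t-test degenerate")
  }
  if (variant == "welch") {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    tstat <- (a$mean - b$mean) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    tstat <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction by default (the convention that reproduces the
#' published gender comparison); set `correct = TRUE` for Yates.
#'
#' @param counts 2x2 matrix of non-negative counts with positive marginals.
#' @param correct Apply the Yates continuity correction.
#' @return List with `chi2`, `df` (1), `p`.
#' @export
chi_square_2x2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!identical(dim(counts), c(2L, 2L)) || any(counts < 0)) {
    stop_invalid("`counts` must be a 2x2 matrix of non-negative counts")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop_invalid("all table marginals must be positive")
  }
  n <- sum(counts)
  num <- abs(counts[1, 1] * counts[2, 2] - counts[1, 2] * counts[2, 1])
  if (correct) num <- max(0, num - n / 2)
  chi2 <- n * num^2 /
    (prod(rowSums(counts)) * prod(colSums(counts)))
  list(chi2 = chi2, df = 1L, p = pchisq(chi2, 1, lower.tail = FALSE))
}

#' Per-group sample size for a two-sample t-test
#'
#' Smallest n per group at which a two-sided two-sample t-test at level
#' `alpha` attains the target power for standardized difference `d`
#' (noncentral-t power, scanned over n).
#'
#' @param effect_size_d Standardized mean difference (> 0).
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return Integer n per group.
#' @export
sample_size_per_group <- function(effect_size_d, alpha = 0.05, power = 0.8) {
  if (effect_size_d <= 0) stop_invalid("effect size must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop_invalid("alpha and power must lie in (0, 1)")
  }
  for (n in 2:1e6) {
    pw <- power.t.test(n = n, delta = effect_size_d, sd = 1,
                       sig.level = alpha, type = "two.sample")$power
    if (pw >= power) return(n)
  }
  stop_invalid("target power unattainable")
}

#' Demographic and clinical comparison table
#'
#' Per-group n/mean/sd and between-group p-value for each numeric clinical
#' measure, plus a chi-square comparison of the gender split — the standard
#' demographics table of a two-group study.
#'
#' @param subjects Subject data.frame with a `group` column, a `gender`
#'   column, and numeric measures.
#' @param measures Numeric columns to summarize (default: all numeric except
#'   identifiers).
#' @param variant t-test variant, see [two_sample_t()].
#' @return Data.frame with one row per measure: group summaries formatted as
#'   "mean (sd)", test name and p-value.
#' @export
clinical_table <- function(subjects, measures = NULL,
                           variant = c("welch", "student")) {
  variant <- match.arg(variant)
  groups <- sort(unique(subjects$group))
  if (length(groups) != 2L) stop_invalid("need exactly two groups")
  if (is.null(measures)) {
    measures <- names(subjects)[vapply(subjects, is.numeric, logical(1))]
  }
  rows <- lapply(measures, function(m) {
    s <- lapply(groups, function(g) {
      v <- subjects[[m]][subjects$group == g]
      group_summary(length(v), mean(v), sd(v))
    })
    tt <- two_sample_t(s[[1]], s[[2]], variant = variant)
    data.frame(measure = m,
               g1 = sprintf("%.1f (%.1f)", s[[1]]$mean, s[[1]]$sd),
               g2 = sprintf("%.1f (%.1f)", s[[2]]$mean, s[[2]]$sd),
               test = paste0("t (", variant, ")"), p = tt$p)
  })
  if ("gender" %in% names(subjects)) {
    tab <- table(subjects$group, subjects$gender)
    cs <- chi_square_2x2(tab)
    rows <- c(rows, list(data.frame(
      measure = "gender",
      g1 = paste(tab[1, ], collapse = "/"),
      g2 = paste(tab[2, ], collapse = "/"),
      test = "chi-square", p = cs$p)))
  }
  out <- do.call(rbind, rows)
  names(out)[2:3] <- groups
  out
}
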