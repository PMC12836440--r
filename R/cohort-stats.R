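# Cohort statistical layer: descriptives, Shapiro-Wilk-gated two-group
# tests with pooled-SD effect sizes, Bonferroni correction, and ICC(2,1)
# observer agreement.

#' Per-cell descriptive statistics of condylar FD
#'
#' One row per (group, age band, gender) cell and per (group, age band)
#' overall cell, with count, mean and sample SD (n - 1 denominator) of
#' both condyles. Cells with a single subject keep their mean but carry
#' `NA` SD; empty cells are kept with `n = 0`, never dropped.
#'
#' @param cohort data frame as produced by [simulate_cohort()].
#' @return Data frame with columns `group`, `age_group`, `stratum`, `n`,
#'   `lc_mean`, `lc_sd`, `rc_mean`, `rc_sd`.
#' @export
descriptive_stats <- function(cohort) {
  check_cohort(cohort)
  if ("age_group" %in% names(cohort)) band <- cohort$age_group
  else band <- age_to_band(cohort$age)
  grid <- expand.grid(group = unique(cohort$group),
                      age_group = unique(band),
                      stratum = c(unique(cohort$gender), "overall"),
                      stringsAsFactors = FALSE)
  cell <- function(g, a, s) {
    sel <- cohort$group == g & band == a
    if (s != "overall") sel <- sel & cohort$gender == s
    lc <- cohort$lc_fd[sel]; rc <- cohort$rc_fd[sel]
    data.frame(group = g, age_group = a, stratum = s, n = sum(sel),
               lc_mean = if (sum(sel) > 0L) mean(lc) else NA_real_,
               lc_sd   = if (sum(sel) > 1L) stats::sd(lc) else NA_real_,
               rc_mean = if (sum(sel) > 0L) mean(rc) else NA_real_,
               rc_sd   = if (sum(sel) > 1L) stats::sd(rc) else NA_real_)
  }
  out <- do.call(rbind, Map(cell, grid$group, grid$age_group, grid$stratum))
  rownames(out) <- NULL
  out[order(out$group, out$age_group, out$stratum), ]
}

check_cohort <- function(cohort) {
  req <- c("group", "age", "gender", "lc_fd", "rc_fd")
  req <- setdiff(req, if ("age_group" %in% names(cohort)) "age" else character())
  missing_cols <- setdiff(req, names(cohort))
  if (length(missing_cols) > 0L)
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  invisible(cohort)
}

#' Shapiro-Wilk normality check
#'
#' Standard Shapiro-Wilk W and p; `is_normal` is `p >= 0.05`, the gate
#' used to choose between the t-test and the Mann-Whitney U test.
#'
#' @param values numeric vector, `n >= 3`.
#' @return List with `W`, `p`, `is_normal`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L)
    stop("Shapiro-Wilk needs at least 3 observations", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("Shapiro-Wilk undefined for zero-variance data", call. = FALSE)
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value,
       is_normal = sw$p.value >= 0.05)
}

#' Cohen's d from summary moments
#'
#' Standardized mean difference with the pooled sample SD:
#' `d = (m1 - m2) / sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#' For patient-vs-control comparisons the patient moments go first, so a
#' negative d means lower FD in patients.
#'
#' @param m1,s1,n1 mean, SD and size of the first group.
#' @param m2,s2,n2 mean, SD and size of the second group.
#' @return Cohen's d (scalar).
#' @export
#' @examples
#' cohens_d(1.2198, 0.102968, 24, 1.321625, 0.059357, 24)  # -1.2116
cohens_d <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2L || n2 < 2L) stop("both groups need n >= 2", call. = FALSE)
  if (s1 < 0 || s2 < 0 || (s1 == 0 && s2 == 0))
    stop("pooled SD must be positive", call. = FALSE)
  pooled <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  (m1 - m2) / pooled
}

#' Normality-gated two-group comparison
#'
#' Runs Shapiro-Wilk on each arm; if both are normal (p >= 0.05) the
#' two-sided equal-variance independent t-test is used, otherwise the
#' two-sided Mann-Whitney U test. Cohen's d from the sample moments is
#' always reported (patient minus control over pooled SD).
#'
#' @param patient_values,control_values numeric vectors, each `n >= 3`.
#' @param alpha significance level for the pre-correction flag.
#' @return List of class `group_comparison`: `test_name`, `statistic`,
#'   `p_value`, `cohens_d`, per-arm means/SDs/sizes, `significant`.
#' @export
compare_groups <- function(patient_values, control_values, alpha = 0.05) {
  if (length(patient_values) < 3L || length(control_values) < 3L)
    stop("both arms need n >= 3", call. = FALSE)
  both_normal <- shapiro_wilk(patient_values)$is_normal &&
                 shapiro_wilk(control_values)$is_normal
  if (both_normal) {
    ht <- stats::t.test(patient_values, control_values, var.equal = TRUE)
    test_name <- "independent t-test"
  } else {
    ht <- stats::wilcox.test(patient_values, control_values, exact = FALSE)
    test_name <- "Mann-Whitney U test"
  }
  d <- cohens_d(mean(patient_values), stats::sd(patient_values),
                length(patient_values),
                mean(control_values), stats::sd(control_values),
                length(control_values))
  structure(list(
    test_name = test_name, statistic = unname(ht$statistic),
    p_value = ht$p.value, cohens_d = d,
    mean_patient = mean(patient_values), mean_control = mean(control_values),
    sd_patient = stats::sd(patient_values),
    sd_control = stats::sd(control_values),
    n_patient = length(patient_values), n_control = length(control_values),
    significant = ht$p.value < alpha), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.6g, Cohen's d = %.4f%s\n",
              x$test_name, x$statistic, x$p_value, x$cohens_d,
              if (x$significant) " (significant at 0.05)" else ""))
  invisible(x)
}

#' Bonferroni correction
#'
#' Each corrected p-value is `min(1, p * m)`; ordering of the input is
#' preserved and a corrected value is never smaller than the raw one.
#'
#' @param p_values numeric vector of raw p-values.
#' @param m number of comparisons (`>=` the number of p-values); defaults
#'   to `length(p_values)`.
#' @return Numeric vector of corrected p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < length(p_values))
    stop("m must be at least the number of p-values", call. = FALSE)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  pmin(1, p_values * m)
}

#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' Intraclass correlation for inter-observer agreement from the standard
#' mean-squares decomposition of a complete subjects x raters matrix, with
#' the F-based 95% confidence interval of McGraw & Wong.
#'
#' @param ratings numeric matrix, rows = subjects (>= 5), columns =
#'   raters (>= 2), no missing cells.
#' @param conf_level confidence level for the interval.
#' @return List with `icc`, `ci_low`, `ci_high`.
#' @export
icc_2_1 <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings matrix must be complete", call. = FALSE)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L || k < 2L)
    stop("need at least 5 subjects and 2 raters", call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)              # between subjects
  msc <- n * sum((col_m - grand)^2) / (k - 1)              # between raters
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
              outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))                          # residual
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  if (mse == 0 && msc == msr) return(list(icc = 1, ci_low = 1, ci_high = 1))
  # Satterthwaite df for the absolute-agreement interval
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
       ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, ci_low = ci_low, ci_high = ci_high)
}

#' Normality table per cell
#'
#' Shapiro-Wilk W, p and the TRUE/FALSE normality verdict for LC and RC FD
#' in every (group, age band) cell.
#'
#' @param cohort cohort data frame.
#' @return Data frame with one row per (group, age band).
#' @export
normality_table <- function(cohort) {
  check_cohort(cohort)
  band <- if ("age_group" %in% names(cohort)) cohort$age_group
          else age_to_band(cohort$age)
  grid <- expand.grid(group = unique(cohort$group),
                      age_group = sort(unique(band)),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- cohort$group == grid$group[i] & band == grid$age_group[i]
    lc <- shapiro_wilk(cohort$lc_fd[sel]); rc <- shapiro_wilk(cohort$rc_fd[sel])
    data.frame(group = grid$group[i], age_group = grid$age_group[i],
               lc_W = lc$W, lc_p = lc$p, lc_normal = lc$is_normal,
               rc_W = rc$W, rc_p = rc$p, rc_normal = rc$is_normal)
  })
  do.call(rbind, rows)
}

#' Patient-vs-control comparisons per age band and condyle
#'
#' For every (age band, condyle) stratum, applies the normality-gated
#' comparison of [compare_groups()] between patients and controls.
#'
#' @param cohort cohort data frame.
#' @param alpha significance level.
#' @return Data frame with one row per (age band, condyle).
#' @export
comparison_table <- function(cohort, alpha = 0.05) {
  check_cohort(cohort)
  band <- if ("age_group" %in% names(cohort)) cohort$age_group
          else age_to_band(cohort$age)
  grid <- expand.grid(age_group = sort(unique(band)),
                      condyle = c("LC_FD", "RC_FD"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    col <- if (grid$condyle[i] == "LC_FD") "lc_fd" else "rc_fd"
    sel <- band == grid$age_group[i]
    cmp <- compare_groups(cohort[[col]][sel & cohort$group == "patient"],
                          cohort[[col]][sel & cohort$group == "control"],
                          alpha = alpha)
    data.frame(age_group = grid$age_group[i], condyle = grid$condyle[i],
               test_name = cmp$test_name, p_value = cmp$p_value,
               cohens_d = cmp$cohens_d,
               mean_patient = cmp$mean_patient,
               mean_control = cmp$mean_control,
               sd_patient = cmp$sd_patient, sd_control = cmp$sd_control,
               significant = cmp$significant)
  })
  out <- do.call(rbind, rows)
  out[order(out$age_group, out$condyle), ]
}

#' Gender-wise comparison of combined left + right condyle FD
#'
#' For each (age band, gender) stratum, pools each subject's LC and RC
#' values per arm, compares patients vs controls with the normality-gated
#' test, and Bonferroni-corrects across the 8 strata. Significance tiers
#' on the corrected p-value: `Not Significant` (>= 0.05),
#' `Significant (**)` (< 0.05), `Highly Significant (***)` (< 0.005) —
#' a presentation rule only.
#'
#' @param cohort cohort data frame.
#' @return Data frame with one row per (age band, gender), 8 rows for the
#'   standard four-band two-gender design.
#' @export
combined_condyle_table <- function(cohort) {
  check_cohort(cohort)
  band <- if ("age_group" %in% names(cohort)) cohort$age_group
          else age_to_band(cohort$age)
  grid <- expand.grid(age_group = sort(unique(band)),
                      gender = sort(unique(cohort$gender)),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- band == grid$age_group[i] & cohort$gender == grid$gender[i]
    pat <- sel & cohort$group == "patient"
    ctl <- sel & cohort$group == "control"
    pv <- c(cohort$lc_fd[pat], cohort$rc_fd[pat])
    cv <- c(cohort$lc_fd[ctl], cohort$rc_fd[ctl])
    cmp <- compare_groups(pv, cv)
    data.frame(age_group = grid$age_group[i], gender = grid$gender[i],
               mean_patient = cmp$mean_patient, sd_patient = cmp$sd_patient,
               mean_control = cmp$mean_control, sd_control = cmp$sd_control,
               difference = cmp$mean_control - cmp$mean_patient,
               test_name = cmp$test_name, p_value = cmp$p_value,
               cohens_d = cmp$cohens_d)
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- bonferroni(out$p_value, m = nrow(out))
  out$significance <- ifelse(out$p_corrected < 0.005, "Highly Significant (***)",
                      ifelse(out$p_corrected < 0.05, "Significant (**)",
                             "Not Significant"))
  out
}
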