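# Cohort-level statistical workflow on participant summary tables:
# sex-specific fitness tertiles and BMI categories, age-sex cell weighting,
# partial Spearman correlations controlled for age, age^2 and sex, and
# Kruskal-Wallis group comparisons with Dunn-Bonferroni post-hoc tests.

#' Assign fitness tertiles and BMI categories
#'
#' Cardiorespiratory-fitness groups are sex-specific VO2max tertiles (low,
#' mid, high). BMI categories cut at 25 and 30 kg/m^2: low below 25, mid from
#' 25 to 30 (inclusive), high above 30. Subjects with a missing covariate are
#' flagged `NA` in the affected scheme.
#'
#' @param cohort Cohort data frame with `sex`, `vo2max`, `bmi`.
#' @return `cohort` with added factor columns `crf_third` and `bmi_category`
#'   (levels low, mid, high).
#' @export
assign_groups <- function(cohort) {
  need <- c("sex", "vo2max", "bmi")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop_format("cohort missing columns: ", paste(miss, collapse = ", "))
  lv <- c("low", "mid", "high")
  crf <- rep(NA_character_, nrow(cohort))
  for (s in unique(cohort$sex[!is.na(cohort$sex)])) {
    i <- which(cohort$sex == s & !is.na(cohort$vo2max))
    if (length(i) < 3L) next
    q <- quantile(cohort$vo2max[i], c(1 / 3, 2 / 3), names = FALSE)
    crf[i] <- lv[findInterval(cohort$vo2max[i], q, left.open = TRUE) + 1L]
  }
  bmi_cat <- ifelse(is.na(cohort$bmi), NA_character_,
                    ifelse(cohort$bmi < 25, "low",
                           ifelse(cohort$bmi <= 30, "mid", "high")))
  out <- cohort
  out$crf_third <- factor(crf, levels = lv)
  out$bmi_category <- factor(bmi_cat, levels = lv)
  out
}

#' Sex-specific VO2max tertile boundaries
#'
#' Convenience accessor for the cut values used by [assign_groups()].
#'
#' @param cohort Cohort data frame with `sex` and `vo2max`.
#' @return Data frame with `sex`, `tertile_1`, `tertile_2`.
#' @export
crf_tertile_cuts <- function(cohort) {
  do.call(rbind, lapply(split(cohort$vo2max, cohort$sex), function(v) {
    q <- quantile(v, c(1 / 3, 2 / 3), na.rm = TRUE, names = FALSE)
    data.frame(tertile_1 = q[1], tertile_2 = q[2])
  })) -> cuts
  data.frame(sex = rownames(cuts), cuts, row.names = NULL)
}

#' Age-sex cell weights
#'
#' Weights each subject by `target share / observed share` of its sex-by-age
#' cell (five age groups 20-29, ..., 60-70 for each sex), under the assumption
#' that the cells are equally sized at the population level. Target shares are
#' equal across the non-empty cells.
#'
#' @param cohort Cohort data frame with `age` and `sex`.
#' @return Positive numeric weight per subject (`NA` where age or sex is
#'   missing). After weighting, every non-empty cell carries the same total
#'   weight.
#' @export
compute_weights <- function(cohort) {
  age_group <- cut(cohort$age, breaks = c(20, 30, 40, 50, 60, 71),
                   right = FALSE, include.lowest = TRUE,
                   labels = c("20-29", "30-39", "40-49", "50-59", "60-70"))
  if (any(is.na(age_group) & !is.na(cohort$age)))
    warning("ages outside 20-70 fall in no weighting cell")
  cell <- interaction(cohort$sex, age_group, drop = FALSE)
  counts <- table(cell)
  nonempty <- sum(counts > 0)
  if (nonempty < length(counts))
    warning(sprintf("%d of %d sex-age cells are empty; targets spread over non-empty cells",
                    length(counts) - nonempty, length(counts)))
  n <- sum(counts)
  target <- 1 / nonempty
  w <- target / (as.numeric(counts[cell]) / n)
  w[is.na(cell)] <- NA_real_
  as.numeric(w)
}

# Weighted Pearson correlation of two centered-by-regression residual vectors.
.wcor <- function(x, y, w) {
  mx <- sum(w * x) / sum(w); my <- sum(w * y) / sum(w)
  sum(w * (x - mx) * (y - my)) /
    sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
}

#' Partial Spearman correlation controlled for age, age-squared and sex
#'
#' Rank-transforms `x` and `y` (average ranks for ties), residualizes each on
#' an intercept, centered age, centered-age squared and a sex indicator by
#' (weighted) least squares, and returns the (weighted) product-moment
#' correlation of the residuals. Weights act as frequency-style weights in the
#' means and cross-products.
#'
#' @param x,y Numeric vectors.
#' @param age Age in years.
#' @param sex Two-level sex labels.
#' @param weights Optional positive weights (default: equal).
#' @return List with `estimate`, `n` and `df` (n minus covariates minus 2).
#' @export
partial_spearman <- function(x, y, age, sex, weights = NULL) {
  n <- length(x)
  if (length(y) != n || length(age) != n || length(sex) != n)
    stop_config("x, y, age, sex must have equal length")
  keep <- stats::complete.cases(x, y, age, sex)
  x <- x[keep]; y <- y[keep]; age <- age[keep]; sex <- sex[keep]
  w <- if (is.null(weights)) rep(1, sum(keep)) else weights[keep]
  if (any(w <= 0)) stop_data("weights must be positive")
  n <- length(x)
  ac <- age - mean(age)
  X <- cbind(1, ac, ac^2, as.numeric(factor(sex)) - 1)
  if (n < ncol(X) + 2L) stop_data("too few observations for partial correlation")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("constant input; correlation undefined")
    return(list(estimate = NA_real_, n = n, df = n - ncol(X) - 2L))
  }
  rx <- rank(x); ry <- rank(y)
  fit <- stats::lm.wfit(X, cbind(rx, ry), w)
  res <- fit$residuals
  list(estimate = .wcor(res[, 1], res[, 2], w), n = n, df = n - ncol(X) - 2L)
}

#' Kruskal-Wallis group comparison with Dunn-Bonferroni post-hoc tests
#'
#' Omnibus Kruskal-Wallis H (delegated to [stats::kruskal.test()]) followed by
#' Dunn's pairwise z statistics on the joint ranks with the ties correction,
#' Bonferroni-adjusted over all pairs. Tests run unweighted.
#'
#' @param values Numeric response (e.g. per-bin minutes).
#' @param groups Group labels (at least two groups of at least two subjects).
#' @return List with `statistic` (H), `df`, `p.value` and `pairwise` (data
#'   frame: `group1`, `group2`, `z`, `p`, `p_adj`).
#' @export
group_compare <- function(values, groups) {
  keep <- stats::complete.cases(values, groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  k <- nlevels(groups)
  if (k < 2L) stop_config("at least two groups are required")
  if (any(table(groups) < 2L)) stop_config("each group needs at least two subjects")
  kw <- kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ni <- table(groups)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(levels(groups), 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(s2 * (1 / ni[[a]] + 1 / ni[[b]]))
    z[j] <- (rbar[[a]] - rbar[[b]]) / se
    p[j] <- 2 * pnorm(-abs(z[j]))
  }
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p.value = kw$p.value,
       pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             z = z, p = p,
                             p_adj = pmin(1, p * ncol(pairs))))
}
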