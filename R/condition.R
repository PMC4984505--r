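#' Fit the length-weight allometry and test slope homogeneity
#'
#' Ordinary least squares of `log10(W)` on `log10(L)` over all individuals,
#' plus per-group fits and an ANCOVA (`log10(W) ~ log10(L) * group`) whose
#' interaction terms test whether one common slope is defensible across
#' groups (cohorts).
#'
#' @param tbl data.frame with columns `weight`, `length` and the grouping
#'   column (weights in g, lengths in mm; any consistent units work, the
#'   intercept absorbs the scale).
#' @param grouping name of the grouping column (default `"cohort"`).
#' @return list with `a` (intercept back-transformed, `10^intercept`), `b`
#'   (common slope), `r` (correlation of the log-log fit), `fit` (the lm),
#'   `by_group` (per-group a, b, r, n), `ancova` (coefficient t-table of
#'   the interaction model) and `ancova_anova` (sequential F table).
#' @export
allometry_fit <- function(tbl, grouping = "cohort") {
  need <- c("weight", "length", grouping)
  if (!all(need %in% names(tbl))) {
    stop("phenotype table needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(tbl) < 3L) stop("need at least 3 individuals")
  if (any(tbl$weight <= 0 | tbl$length <= 0)) {
    stop("weights and lengths must be positive")
  }
  lw <- log10(tbl$weight)
  ll <- log10(tbl$length)
  fit <- stats::lm(lw ~ ll)
  grp <- factor(tbl[[grouping]])
  by_group <- do.call(rbind, lapply(levels(grp), function(gl) {
    idx <- grp == gl
    f <- stats::lm(lw[idx] ~ ll[idx])
    data.frame(group = gl, n = sum(idx),
               a = 10^unname(stats::coef(f)[1L]),
               intercept = unname(stats::coef(f)[1L]),
               b = unname(stats::coef(f)[2L]),
               r = stats::cor(lw[idx], ll[idx]),
               stringsAsFactors = FALSE)
  }))
  ct <- NULL; aov_tab <- NULL
  if (nlevels(grp) >= 2L) {
    anc <- stats::lm(lw ~ ll * grp)
    ct <- as.data.frame(summary(anc)$coefficients)
    aov_tab <- stats::anova(anc)
  }
  list(a = 10^unname(stats::coef(fit)[1L]),
       intercept = unname(stats::coef(fit)[1L]),
       b = unname(stats::coef(fit)[2L]),
       r = stats::cor(lw, ll),
       fit = fit, by_group = by_group,
       ancova = ct, ancova_anova = aov_tab)
}

#' Relative condition index Kn
#'
#' `Kn = W / (a * L^b)`: observed weight over the weight predicted by the
#' allometric regression. When `a` and `b` are fitted on the same data the
#' geometric-mean Kn is 1 by construction, so values above/below 1 flag
#' individuals in better/worse condition than the sample average.
#'
#' @param weight,length vectors of positive measurements (units must match
#'   those used to fit `a` and `b`).
#' @param a,b allometry coefficients from [allometry_fit()] (or published
#'   values on the same unit scale).
#' @return vector of Kn > 0.
#' @export
condition_index <- function(weight, length, a, b) {
  if (any(weight <= 0 | length <= 0)) stop("measurements must be positive")
  weight / (a * length^b)
}

#' Heterozygosity-fitness linear model for the condition index
#'
#' Fits the nested model `Kn ~ Rds * IR * (cohort / matriline)` where `Rds`
#' is the residual of the HL-on-IR regression (so the two homozygosity
#' indices enter without collinearity) and matriline is nested in cohort.
#' F tests are sequential (type I), in increasing interaction order.
#'
#' @param df data.frame with columns `kn`, `hl`, `ir`, `cohort`,
#'   `matriline`; rows with any NA are dropped (reported).
#' @return list with `anova` (sequential F table), `fit`, `rds` (residual
#'   vector), `n_dropped`.
#' @export
hfc_model <- function(df) {
  need <- c("kn", "hl", "ir", "cohort", "matriline")
  if (!all(need %in% names(df))) {
    stop("need columns ", paste(need, collapse = ", "))
  }
  keep <- stats::complete.cases(df[, need])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("hfc_model: dropped ", n_dropped, " incomplete row(s)")
  }
  df <- df[keep, ]
  df$cohort <- factor(df$cohort)
  df$matriline <- factor(df$matriline)
  rfit <- stats::lm(hl ~ ir, data = df)
  df$rds <- stats::resid(rfit)
  fit <- stats::lm(kn ~ rds * ir * (cohort / matriline), data = df)
  list(anova = stats::anova(fit), fit = fit, rds = df$rds,
       n_dropped = n_dropped)
}
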