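# Nonparametric agreement statistics between paired SPECT and PET
# measurements. Sign convention used throughout the package: relative
# differences are d = 100 * (PET - SPECT) / SPECT, so positive medians
# mean PET reads higher.

#' Ordinary least-squares fit
#'
#' Simple linear regression `y = slope * x + intercept` with the
#' coefficient of determination `R^2 = 1 - SS_res / SS_tot`. When `y`
#' is constant, `R^2` is defined as 0 (SS_tot = 0 convention).
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`; `x` must not
#'   be constant.
#' @return A list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
least_squares_fit <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y) || n < 3L || anyNA(x) || anyNA(y)) {
    abort_suvpair("x and y must be equal-length numeric vectors, n >= 3, no NA",
                  "suvpair_invalid_argument")
  }
  if (stats::sd(x) == 0) {
    abort_suvpair("x is constant; regression is degenerate",
                  "suvpair_degenerate_input")
  }
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = max(0, min(1, r2)), n = n)
}

# Percentile by linear interpolation between order statistics at
# h = (n - 1) p + 1 (R's quantile type 7).
percentile_interp <- function(x, p) {
  as.numeric(stats::quantile(x, probs = p, type = 7, names = FALSE))
}

#' Nonparametric Bland-Altman summary
#'
#' Pairwise agreement between modalities summarized by the median and
#' the empirical 2.5th/97.5th percentiles (95% limits of agreement) of
#' the per-lesion relative differences
#' `d_i = 100 * (PET_i - SPECT_i) / SPECT_i` (`normalize = "spect"`),
#' or of raw differences `PET_i - SPECT_i` (`normalize = "none"`).
#' The median/percentile construction is used instead of mean +- 1.96 SD
#' because SUV differences are typically not normally distributed.
#' Percentiles interpolate linearly between order statistics at
#' `h = (n - 1) p + 1`.
#'
#' @param spect_vals,pet_vals Equal-length numeric vectors, `n >= 3`.
#' @param normalize `"spect"` (percent differences relative to SPECT)
#'   or `"none"` (raw differences).
#' @return A list with `median_diff`, `loa_low`, `loa_high` (2.5th and
#'   97.5th percentiles), `n`, `normalization`, plus plotting vectors
#'   `pair_means` (x-axis: mean of the two values) and `differences`.
#' @export
bland_altman_median <- function(spect_vals, pet_vals,
                                normalize = c("spect", "none")) {
  normalize <- match.arg(normalize)
  s <- as.numeric(spect_vals); p <- as.numeric(pet_vals)
  n <- length(s)
  if (n != length(p) || n < 3L || anyNA(s) || anyNA(p)) {
    abort_suvpair("inputs must be equal-length numeric vectors, n >= 3, no NA",
                  "suvpair_invalid_argument")
  }
  if (normalize == "spect") {
    if (any(s <= 0)) {
      abort_suvpair("all SPECT values must be > 0 to normalize differences",
                    "suvpair_invalid_argument")
    }
    d <- 100 * (p - s) / s
  } else {
    d <- p - s
  }
  list(median_diff = stats::median(d),
       loa_low = percentile_interp(d, 0.025),
       loa_high = percentile_interp(d, 0.975),
       n = n,
       normalization = if (normalize == "spect") "relative to SPECT" else "raw",
       pair_means = (s + p) / 2,
       differences = d)
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Tests whether paired differences are symmetric about zero. Zero
#' differences are dropped before ranking (classical convention). For
#' `n <= 25` nonzero differences without ties in `|d|`, the exact null
#' distribution of the positive-rank sum is used; otherwise a normal
#' approximation with tie correction and continuity correction. The
#' branch taken is recorded in the result.
#'
#' @param differences Numeric vector of paired differences.
#' @param exact_max Largest `n` for which the exact branch is used
#'   (default 25).
#' @return A list with `statistic` (positive-rank sum V), `p_value`
#'   (two-sided), `n` (nonzero differences), `method` (`"exact"` or
#'   `"normal_approx"`).
#' @export
wilcoxon_signed_rank <- function(differences, exact_max = 25L) {
  d <- as.numeric(differences)
  if (anyNA(d)) {
    abort_suvpair("differences must not contain NA", "suvpair_invalid_argument")
  }
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    abort_suvpair("all differences are zero; test is degenerate",
                  "suvpair_degenerate_input")
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0L
  if (n <= exact_max && !has_ties) {
    # exact: V ~ signrank(n) under H0
    p_le <- stats::psignrank(v, n)
    p_ge <- 1 - stats::psignrank(v - 1, n)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  list(statistic = v, p_value = p, n = n, method = method)
}

#' Mann-Whitney U test for two independent groups
#'
#' Tests whether values in one group tend to exceed those in the other
#' (e.g. metastatic versus benign lesion SUVs). For combined
#' `m + n <= 20` without ties the exact null distribution of U is used;
#' otherwise a normal approximation with tie correction and continuity
#' correction. `alternative = "greater"` tests the directional
#' hypothesis that `group_a` is stochastically larger.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @param exact_max Largest combined sample size for the exact branch
#'   (default 20).
#' @return A list with `statistic` (U for `group_a`), `p_value`, `n_a`,
#'   `n_b`, `method`.
#' @export
mann_whitney_u <- function(group_a, group_b,
                           alternative = c("two.sided", "greater"),
                           exact_max = 20L) {
  alternative <- match.arg(alternative)
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) == 0L || length(b) == 0L || anyNA(a) || anyNA(b)) {
    abort_suvpair("both groups must be non-empty with no NA",
                  "suvpair_invalid_argument")
  }
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2  # number of (a > b) pairs + ties/2
  has_ties <- anyDuplicated(c(a, b)) > 0L
  if (m + n <= exact_max && !has_ties) {
    p_le <- stats::pwilcox(u, m, n)
    p_ge <- 1 - stats::pwilcox(u - 1, m, n)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge)
    method <- "exact"
  } else {
    mu <- m * n / 2
    ntot <- m + n
    ties <- table(c(a, b))
    sigma2 <- m * n / 12 * (ntot + 1 - sum(ties^3 - ties) / (ntot * (ntot - 1)))
    if (sigma2 <= 0) {
      abort_suvpair("all values tied; test is degenerate",
                    "suvpair_degenerate_input")
    }
    z_num <- u - mu
    z <- (z_num - sign(z_num) * 0.5) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE))
    method <- "normal_approx"
  }
  list(statistic = u, p_value = min(1, p), n_a = m, n_b = n, method = method)
}

#' Shapiro-Wilk normality gate
#'
#' Used to justify median/percentile summaries: when the Shapiro-Wilk
#' test rejects normality (p <= 0.05), nonparametric summaries are
#' reported. Delegates to the standard published algorithm
#' (`stats::shapiro.test`).
#'
#' @param values Numeric vector, `3 <= n <= 5000`, non-constant.
#' @param alpha Significance level for the flag (default 0.05).
#' @return A list with `is_normal` (p > alpha), `p_value`, `W`, `n`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 3L || n > 5000L || anyNA(x)) {
    abort_suvpair("n must be in [3, 5000] with no NA", "suvpair_invalid_argument")
  }
  if (stats::sd(x) == 0) {
    abort_suvpair("values have zero variance; W is undefined",
                  "suvpair_degenerate_input")
  }
  sw <- stats::shapiro.test(x)
  list(is_normal = unname(sw$p.value > alpha),
       p_value = unname(sw$p.value), W = unname(sw$statistic), n = n)
}

#' Median (IQR) differences stratified by lesion size
#'
#' Partitions lesions into equal-count volume strata (quartiles by
#' default) and reports, per stratum and SUV measure, the median and
#' interquartile range of the relative differences
#' `100 * (PET - SPECT) / SPECT`. Smaller lesions are expected to show
#' larger differences when the reference modality has better spatial
#' resolution (partial volume effect).
#'
#' @param paired A paired-lesion data.frame as produced by
#'   [pair_lesion_records()]: one row per lesion with `volume_cm3` and
#'   `spect_<m>` / `pet_<m>` columns for each measure in `measures`.
#' @param measures Character vector of measure suffixes (default
#'   `c("suv_max", "suv_peak", "suv_mean")`).
#' @param n_strata Number of equal-count volume strata (default 4).
#' @return A data.frame with one row per stratum x measure: `stratum`,
#'   `volume_min`, `volume_max`, `n`, `measure`, `median_diff_pct`,
#'   `iqr_low_pct`, `iqr_high_pct`.
#' @export
size_stratified_summary <- function(paired,
                                    measures = c("suv_max", "suv_peak", "suv_mean"),
                                    n_strata = 4L) {
  if (!is.data.frame(paired) || nrow(paired) < n_strata) {
    abort_suvpair("need at least as many records as strata",
                  "suvpair_invalid_argument")
  }
  v <- paired$volume_cm3
  # equal-count strata: order by volume, split into n_strata chunks whose
  # sizes differ by at most one (largest chunks first, mirroring e.g. a
  # 58/58/58/57 split of 231)
  ord <- order(v)
  n <- length(v)
  base <- n %/% n_strata
  extra <- n %% n_strata
  sizes <- rep(base, n_strata) + c(rep(1L, extra), rep(0L, n_strata - extra))
  stratum <- integer(n)
  stratum[ord] <- rep(seq_len(n_strata), times = sizes)
  out <- list()
  for (s in seq_len(n_strata)) {
    sel <- stratum == s
    for (m in measures) {
      sv <- paired[[paste0("spect_", m)]][sel]
      pv <- paired[[paste0("pet_", m)]][sel]
      d <- 100 * (pv - sv) / sv
      out[[length(out) + 1L]] <- data.frame(
        stratum = s,
        volume_min = min(v[sel]), volume_max = max(v[sel]),
        n = sum(sel), measure = m,
        median_diff_pct = stats::median(d),
        iqr_low_pct = percentile_interp(d, 0.25),
        iqr_high_pct = percentile_interp(d, 0.75)
      )
    }
  }
  do.call(rbind, out)
}

#' Per-site background SUV summary
#'
#' Median (IQR) of the background bone SUV_mean per skeletal site and
#' modality, plus the paired Wilcoxon signed-rank p-value for the
#' PET - SPECT background difference at each site.
#'
#' @param paired A paired-lesion data.frame with columns `site`,
#'   `spect_suv_mean_bg`, `pet_suv_mean_bg`.
#' @param sites Site labels to report; defaults to those present.
#' @return A data.frame with one row per site: medians and IQRs per
#'   modality, the median (IQR) paired difference, `n`, and
#'   `wilcoxon_p`.
#' @export
site_background_summary <- function(paired, sites = NULL) {
  known <- c("skull", "spine", "rib_cage", "pelvis", "limbs")
  if (is.null(sites)) sites <- intersect(known, unique(paired$site))
  if (!all(sites %in% known)) {
    abort_suvpair(sprintf("unknown site label(s): %s",
                          paste(setdiff(sites, known), collapse = ", ")),
                  "suvpair_invalid_argument")
  }
  out <- list()
  for (st in sites) {
    sel <- paired$site == st
    if (!any(sel)) next
    sb <- paired$spect_suv_mean_bg[sel]
    pb <- paired$pet_suv_mean_bg[sel]
    d <- pb - sb
    wp <- if (all(d == 0)) 1 else wilcoxon_signed_rank(d)$p_value
    out[[length(out) + 1L]] <- data.frame(
      site = st, n = sum(sel),
      pet_median = stats::median(pb),
      pet_iqr_low = percentile_interp(pb, 0.25),
      pet_iqr_high = percentile_interp(pb, 0.75),
      spect_median = stats::median(sb),
      spect_iqr_low = percentile_interp(sb, 0.25),
      spect_iqr_high = percentile_interp(sb, 0.75),
      diff_median = stats::median(d),
      diff_iqr_low = percentile_interp(d, 0.25),
      diff_iqr_high = percentile_interp(d, 0.75),
      wilcoxon_p = wp
    )
  }
  do.call(rbind, out)
}
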