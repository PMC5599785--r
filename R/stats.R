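# Inferential layer: pooled two-sample t-tests per (band, metric) and
# Pearson correlations between alpha-band metrics and smoking covariates.

#' Pooled-variance two-sample t-test
#'
#' Student's t with pooled variance and df = n_a + n_b - 2 (the classical
#' equal-variance form, matching SPSS's default row), two-sided p. Welch's
#' unequal-variance version is returned alongside for reference.
#'
#' @param values_a,values_b Numeric vectors, each with at least 2 values.
#' @return List with `t`, `p`, `df`, `t_welch`, `p_welch`.
#' @export
two_sample_t <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 values")
  }
  if (!all(is.finite(values_a)) || !all(is.finite(values_b))) {
    stop("non-finite values in input")
  }
  out <- two_sample_t_summary(mean(values_a), stats::sd(values_a),
                              length(values_a),
                              mean(values_b), stats::sd(values_b),
                              length(values_b))
  w <- tryCatch(stats::t.test(values_a, values_b, var.equal = FALSE),
                error = function(e) NULL)  # e.g. both groups constant
  out$t_welch <- if (is.null(w)) NA_real_ else unname(w$statistic)
  out$p_welch <- if (is.null(w)) NA_real_ else w$p.value
  out
}

#' Pooled two-sample t-test from summary statistics
#'
#' The closed form `t = (m_a - m_b) / sqrt(s_p^2 (1/n_a + 1/n_b))` with
#' pooled variance `s_p^2 = ((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a+n_b-2)`,
#' usable directly on a published table's means and SDs.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries.
#' @return List with `t`, `p`, `df`.
#' @export
two_sample_t_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  if (sp2 <= 0) {
    if (mean_a == mean_b) stop("t undefined: zero pooled variance, equal means")
    # zero within-group variance but distinct means: the difference is
    # infinitely many standard errors away
    return(list(t = sign(mean_a - mean_b) * Inf, p = 0, df = df))
  }
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  t <- (mean_a - mean_b) / se
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Pearson correlation with two-sided p
#'
#' Sample Pearson r; p from the exact t transform
#' `t = r sqrt((n-2)/(1-r^2))` with df = n - 2.
#'
#' @param x,y Numeric vectors of equal length n >= 3, both non-constant.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs (have ", n, ")")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant input")
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tv <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tv), n - 2)
  }
  list(r = r, p = p, n = n)
}

# long metrics table -> named value vector for one (band, metric) and group
metrics_long <- function(subjects) {
  do.call(rbind, lapply(subjects, function(s) {
    m <- s$metrics
    m$subject_id <- s$record$subject_id
    m$group <- s$record$group
    m
  }))
}

#' Group comparison table over bands and metrics
#'
#' One row per (band, metric) with smoker and nonsmoker mean/SD (n-1
#' denominator), pooled t (sign convention: smoker minus nonsmoker), its
#' two-sided p, Welch auxiliaries, and a Holm-corrected p emitted as a
#' clearly separate extension column. No correction is applied to `p`
#' itself. Significance at alpha = 0.05 is marked in a boolean column.
#'
#' @param subjects List of subjects as produced by the pipeline: each has
#'   `record` (with `group`) and `metrics` (data.frame band, metric, value).
#' @param bands Character vector of band names (default: those present).
#' @param metrics Character vector of metric names (default: those present).
#' @return Data.frame, one row per (band, metric), deterministic order.
#' @export
comparison_table <- function(subjects, bands = NULL, metrics = NULL) {
  long <- metrics_long(subjects)
  if (!all(c("smoker", "nonsmoker") %in% long$group)) {
    stop("both groups (smoker, nonsmoker) must be represented")
  }
  if (is.null(bands)) bands <- unique(long$band)
  if (is.null(metrics)) metrics <- unique(long$metric)
  rows <- list()
  for (b in bands) {
    for (met in metrics) {
      sel <- long[long$band == b & long$metric == met, ]
      va <- sel$value[sel$group == "smoker"]
      vb <- sel$value[sel$group == "nonsmoker"]
      # a metric can be degenerate (identical in both groups) on small or
      # strongly coupled networks; report the row with NA rather than abort
      tt <- tryCatch(two_sample_t(va, vb), error = function(e) {
        list(t = NA_real_, p = NA_real_, t_welch = NA_real_,
             p_welch = NA_real_)
      })
      rows[[length(rows) + 1]] <- data.frame(
        band = b, metric = met,
        mean_smoker = mean(va), sd_smoker = stats::sd(va),
        mean_nonsmoker = mean(vb), sd_nonsmoker = stats::sd(vb),
        t = tt$t, p = tt$p, t_welch = tt$t_welch, p_welch = tt$p_welch)
    }
  }
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out$significant <- out$p < 0.05
  out
}

#' Metric-covariate correlation table within the smoker group
#'
#' One row per (metric, covariate) for a single band; missing covariate
#' values are dropped pairwise with the effective n recorded.
#'
#' @param subjects Subject list (non-smokers are ignored).
#' @param band Band name (default `"alpha"`).
#' @param metrics Metric names (default the four the tree comparison centres
#'   on: eccentricity, diameter, leaf_fraction, kappa).
#' @param covariates Covariate names (default pack_years, ftnd, onset_age,
#'   cigarettes_per_day).
#' @return Data.frame with metric, covariate, r, p, n, significant.
#' @export
correlation_table <- function(subjects, band = "alpha",
                              metrics = c("eccentricity", "diameter",
                                          "leaf_fraction", "kappa"),
                              covariates = c("pack_years", "ftnd",
                                             "onset_age",
                                             "cigarettes_per_day")) {
  smokers <- Filter(function(s) s$record$group == "smoker", subjects)
  if (length(smokers) < 3) stop("need at least 3 smokers")
  rows <- list()
  for (met in metrics) {
    vals <- vapply(smokers, function(s) {
      v <- s$metrics$value[s$metrics$band == band & s$metrics$metric == met]
      if (length(v) == 1) v else NA_real_
    }, numeric(1))
    for (cv in covariates) {
      cov <- vapply(smokers, function(s) {
        x <- s$record[[cv]]
        if (is.null(x)) NA_real_ else as.numeric(x)
      }, numeric(1))
      if (all(!is.finite(cov))) {
        stop("covariate '", cv, "' is missing for every smoker")
      }
      pc <- tryCatch(pearson_cor(vals, cov), error = function(e) {
        list(r = NA_real_, p = NA_real_,
             n = sum(is.finite(vals) & is.finite(cov)))
      })
      rows[[length(rows) + 1]] <- data.frame(
        metric = met, covariate = cv, r = pc$r, p = pc$p, n = pc$n)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p < 0.05
  out
}
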