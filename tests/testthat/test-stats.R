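# Inferential layer: pooled t-tests and Pearson correlations.

test_that("two_sample_t matches the pooled closed form and t.test", {
  r <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # antisymmetry
  set.seed(51)
  a <- rnorm(12)
  b <- rnorm(15, mean = 0.5)
  r1 <- two_sample_t(a, b)
  r2 <- two_sample_t(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  # agreement with stats::t.test(var.equal = TRUE) as reference
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(r1$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r1$p, ref$p.value, tolerance = 1e-12)
  expect_equal(r1$df, unname(ref$parameter))
  # summary form equals the data form for equal n
  a2 <- rnorm(20)
  b2 <- rnorm(20)
  rs <- two_sample_t_summary(mean(a2), sd(a2), 20, mean(b2), sd(b2), 20)
  rd <- two_sample_t(a2, b2)
  expect_equal(rs$t, rd$t, tolerance = 1e-12)
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
  expect_error(two_sample_t_summary(1, 0, 5, 1, 0, 5), "undefined")
})

test_that("p-values are invariant under affine transforms of the data", {
  set.seed(53)
  a <- rnorm(20)
  b <- rnorm(20, 0.8)
  base <- two_sample_t(a, b)
  shifted <- two_sample_t(3 * a - 7, 3 * b - 7)
  expect_equal(shifted$t, base$t, tolerance = 1e-10)
  expect_equal(shifted$p, base$p, tolerance = 1e-10)
})

test_that("pearson_cor reproduces hand-computed values", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_cor(c(1, 2, 3), c(6, 4, 2))$r, -1)
  r <- pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$r, 0.8)
  ref <- stats::cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  # pairwise NA dropping records effective n
  r2 <- pearson_cor(c(1, 2, 3, 4, NA), c(1, 3, 2, 4, 9))
  expect_equal(r2$n, 4)
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_cor(1:2, c(2, 4)), "at least 3")
})

# compact fixture: subjects with a long metrics table
make_subjects <- function(n_per_group = 5, bands = c("alpha", "beta"),
                          metrics = c("pli", "leaf_fraction"), seed = 1) {
  set.seed(seed)
  subs <- list()
  for (g in c("smoker", "nonsmoker")) {
    for (k in seq_len(n_per_group)) {
      grid <- expand.grid(band = bands, metric = metrics,
                          stringsAsFactors = FALSE)
      grid$value <- rnorm(nrow(grid), mean = ifelse(g == "smoker", 0, 0.3))
      subs[[length(subs) + 1]] <- list(
        record = list(subject_id = sprintf("%s%02d", g, k), group = g,
                      ftnd = if (g == "smoker") rnorm(1, 4.6, 1.5) else NA,
                      pack_years = if (g == "smoker") rnorm(1, 3, 1.8) else NA,
                      onset_age = if (g == "smoker") rnorm(1, 15.3) else NA,
                      cigarettes_per_day = if (g == "smoker")
                        rnorm(1, 14.05, 3.9) else NA),
        metrics = grid)
    }
  }
  subs
}

test_that("comparison_table has the full band x metric grid and sane rows", {
  subs <- make_subjects(6, bands = c("delta", "theta", "alpha", "beta"),
                        metrics = c("pli", "degree", "leaf_fraction",
                                    "diameter", "eccentricity", "bc",
                                    "tree_hierarchy", "kappa"))
  tab <- comparison_table(subs)
  expect_equal(nrow(tab), 32)
  expect_true(all(tab$sd_smoker >= 0 & tab$sd_nonsmoker >= 0))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true(all(tab$p_holm >= tab$p - 1e-15))
  # identical groups -> all t exactly 0
  subs_eq <- subs
  for (k in seq_along(subs_eq)) {
    subs_eq[[k]]$metrics$value <- rep(c(0.1, 0.2, 0.4, 0.8), 8)[seq_len(32)] +
      (k %% 6) / 10
  }
  # make value depend only on position within group, not on group
  for (k in seq_along(subs_eq)) {
    subs_eq[[k]]$metrics$value <- subs_eq[[((k - 1) %% 6) + 1]]$metrics$value
  }
  tab_eq <- comparison_table(subs_eq)
  expect_true(all(tab_eq$t == 0))
  # doubling one metric's values leaves its t and p unchanged
  subs_scaled <- subs
  for (k in seq_along(subs_scaled)) {
    sel <- subs_scaled[[k]]$metrics$metric == "kappa"
    subs_scaled[[k]]$metrics$value[sel] <-
      2 * subs_scaled[[k]]$metrics$value[sel]
  }
  t_before <- tab$t[tab$metric == "kappa"]
  tab_scaled <- comparison_table(subs_scaled)
  expect_equal(tab_scaled$t[tab_scaled$metric == "kappa"], t_before,
               tolerance = 1e-10)
  # one group absent -> rejected
  only_smokers <- Filter(function(s) s$record$group == "smoker", subs)
  expect_error(comparison_table(only_smokers), "both groups")
})

test_that("correlation_table covers metric x covariate with pairwise n", {
  subs <- make_subjects(8, bands = "alpha",
                        metrics = c("eccentricity", "diameter",
                                    "leaf_fraction", "kappa"))
  tab <- correlation_table(subs)
  expect_equal(nrow(tab), 16)
  expect_true(all(abs(tab$r) <= 1))
  expect_true(all(tab$n == 8))
  # covariate equal to a metric gives r = 1 on that row
  subs2 <- subs
  for (k in seq_along(subs2)) {
    if (subs2[[k]]$record$group == "smoker") {
      m <- subs2[[k]]$metrics
      subs2[[k]]$record$ftnd <-
        m$value[m$band == "alpha" & m$metric == "kappa"]
    }
  }
  tab2 <- correlation_table(subs2)
  expect_equal(tab2$r[tab2$metric == "kappa" & tab2$covariate == "ftnd"], 1)
  # permuting subject order changes nothing
  tab3 <- correlation_table(rev(subs))
  expect_equal(tab3$r, tab$r)
  # all-missing covariate is named in the error
  subs4 <- subs
  for (k in seq_along(subs4)) subs4[[k]]$record$pack_years <- NA
  expect_error(correlation_table(subs4), "pack_years")
  expect_error(correlation_table(subs[11:16]), "at least 3 smokers")
})
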