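make_cells <- function(n_per_group, means, sds, seed = 1) {
  set.seed(seed)
  conds <- names(means)
  do.call(rbind, lapply(conds, function(g) {
    data.frame(condition = g,
               value = rnorm(n_per_group, means[[g]], sds[[g]]))
  }))
}

test_that("per-cell aggregation averages each parameter within a cell", {
  rec <- data.frame(
    image_id = c("c1", "c1", "c2"), condition = "control",
    area = c(1000, 2000, 1500), area_sq = c(1, 4, 2.25) * 1e6,
    perimeter = c(100, 200, 150), feret = c(40, 60, 50),
    circularity = c(0.8, 0.9, 0.85), roundness = c(0.7, 0.9, 0.8),
    aspect_ratio = c(1.2, 1.4, 1.3), form_factor = c(1.25, 1.11, 1.18)
  )
  cells <- aggregate_per_cell(rec)
  expect_equal(nrow(cells), 2)
  expect_equal(cells$area[cells$image_id == "c1"], 1500)
  expect_equal(cells$n_particles, c(2, 1))
  # the grand mean is the particle-count-weighted mean of cell means
  expect_equal(sum(cells$area * cells$n_particles) / sum(cells$n_particles),
               mean(rec$area))
})

test_that("Shapiro-Wilk wrapper behaves at its limits", {
  scores <- qnorm((1:40 - 0.5) / 40) # perfect normal quantiles
  sw <- shapiro_wilk(scores)
  expect_gt(sw$W, 0.99)
  set.seed(3)
  ps <- replicate(500, shapiro_wilk(rcauchy(50))$p)
  expect_lt(median(ps), 0.05)
  expect_error(shapiro_wilk(rep(2, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("one-way ANOVA reproduces the hand-worked decomposition", {
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("a", "b", "c"), each = 3)
  an <- one_way_anova(vals, grp)
  expect_equal(an$F, 3)
  expect_equal(unname(an$df), c(2, 6))
  expect_equal(an$ss_between, 6)
  expect_equal(an$ss_within, 6)
  # p from an independent route through the F distribution
  expect_equal(an$p, pf(3, 2, 6, lower.tail = FALSE))
  # cross-check the full decomposition against stats::aov
  ref <- summary(stats::aov(vals ~ factor(grp)))[[1]]
  expect_equal(an$F, ref[["F value"]][1])
  expect_equal(an$p, ref[["Pr(>F)"]][1])

  # equal group means with spread: F collapses to 0
  an0 <- one_way_anova(c(1, 3, 1, 3, 1, 3), rep(c("a", "b", "c"), each = 2))
  expect_equal(an0$F, 0)

  expect_error(one_way_anova(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               "variance")
  expect_error(one_way_anova(c(1, 2, 3), c("a", "a", "a")), "two groups")
})

test_that("Dunnett with one treatment reduces to the pooled t-test", {
  set.seed(8)
  x <- rnorm(24, 10, 2); y <- rnorm(24, 11, 2)
  vals <- c(x, y); grp <- rep(c("control", "t1"), each = 24)
  tt <- t.test(y, x, var.equal = TRUE)
  dn_mc <- dunnett(vals, grp, "control", method = "mc", mc_draws = 2e5,
                   seed = 4)
  expect_lt(abs(dn_mc$p_adj - tt$p.value), 0.005)
  dn_mvt <- dunnett(vals, grp, "control", method = "mvt", seed = 4)
  expect_lt(abs(dn_mvt$p_adj - tt$p.value), 0.005)
  expect_equal(dn_mc$t, unname(tt$statistic), tolerance = 1e-9)
})

test_that("Dunnett agrees with multcomp and dominates the unadjusted p", {
  skip_if_not_installed("multcomp")
  set.seed(15)
  vals <- c(rnorm(20, 10), rnorm(24, 10.8), rnorm(18, 9.4))
  grp <- rep(c("control", "t1", "t2"), c(20, 24, 18))
  dn <- dunnett(vals, grp, "control", method = "mvt", seed = 2)
  fit <- multcomp::glht(stats::aov(vals ~ g,
                                   data = data.frame(vals = vals,
                                                     g = factor(grp))),
                        linfct = multcomp::mcp(g = "Dunnett"))
  ref <- summary(fit)$test
  expect_equal(sort(dn$t), sort(unname(ref$tstat)), tolerance = 1e-8)
  expect_lt(max(abs(sort(dn$p_adj) - sort(as.numeric(ref$pvalues)))),
            0.005)
  # adjusted p never undercuts the per-comparison p
  lsd <- fisher_lsd(vals, grp, "control")
  expect_true(all(dn$p_adj >= lsd$p - 1e-9))
  # mc and mvt evaluation methods agree
  dn_mc <- dunnett(vals, grp, "control", method = "mc", mc_draws = 2e5,
                   seed = 9)
  expect_lt(max(abs(dn_mc$p_adj - dn$p_adj)), 0.01)

  expect_error(dunnett(vals, grp, "nope"), "control")
})

test_that("Dunnett detects a 2-SD shift with high power", {
  set.seed(30)
  hits <- vapply(1:200, function(i) {
    vals <- c(rnorm(24, 0, 1), rnorm(24, 2, 1))
    any(dunnett(vals, rep(c("control", "t1"), each = 24), "control",
                method = "mvt", seed = i)$significant)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Fisher's LSD is the unadjusted pooled comparison", {
  set.seed(5)
  x <- rnorm(12, 5); y <- rnorm(12, 6)
  vals <- c(x, y); grp <- rep(c("control", "t1"), each = 12)
  lsd <- fisher_lsd(vals, grp, "control")
  tt <- t.test(y, x, var.equal = TRUE)
  expect_equal(lsd$p, tt$p.value, tolerance = 1e-12)

  # under the null the per-comparison error sits near alpha
  set.seed(77)
  rej <- vapply(1:400, function(i) {
    vals <- rnorm(72)
    grp <- rep(c("control", "t1", "t2"), each = 24)
    fisher_lsd(vals, grp, "control")$significant
  }, logical(2))
  expect_lt(abs(mean(rej) - 0.05), 0.025)
})

test_that("run_group_analysis reports every parameter with SEM = SD/sqrt(n)", {
  set.seed(19)
  cells <- data.frame(
    image_id = sprintf("c%02d", 1:30),
    condition = rep(c("control", "treated"), each = 15)
  )
  for (p in mitomorph:::MORPHO_PARAMETERS)
    cells[[p]] <- rnorm(30, 10, 1)
  res <- run_group_analysis(cells, "control", seed = 3)
  expect_equal(nrow(res$anova), 8)
  expect_equal(nrow(res$dunnett), 8)
  one <- res$means[res$means$parameter == "area" &
                     res$means$condition == "control", ]
  manual <- cells$area[cells$condition == "control"]
  expect_equal(one$sem, sd(manual) / sqrt(15))
  expect_equal(one$mean, mean(manual))
  expect_true(all(c("W", "p") %in% names(res$normality)))
})
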