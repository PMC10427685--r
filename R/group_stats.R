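MORPHO_PARAMETERS <- c("area_sq", "area", "perimeter", "feret",
                       "circularity", "roundness", "aspect_ratio",
                       "form_factor")

#' Aggregate particle records per cell
#'
#' The statistical unit of the morphometric analysis is the cell (one
#' micrograph per cell): each morphological parameter is averaged over a
#' cell's particles, and the per-cell means enter the group tests. Cells
#' with zero particles are omitted with a warning.
#'
#' @param records particle data.frame from [measure_image()] (needs
#'   `image_id` and `condition` columns).
#' @param parameters parameter columns to average.
#' @return A data.frame with one row per cell: `image_id`, `condition`,
#'   `n_particles`, and the per-parameter means.
#' @export
aggregate_per_cell <- function(records, parameters = MORPHO_PARAMETERS) {
  need <- c("image_id", "condition", parameters)
  if (!all(need %in% names(records)))
    stop("records need columns ", paste(setdiff(need, names(records)),
                                        collapse = ", "))
  if (nrow(records) == 0)
    stop("no particle records to aggregate")
  if (anyNA(records$image_id) || anyNA(records$condition))
    stop("every record must carry an image id and a condition")
  split_key <- interaction(records$image_id, records$condition, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, split_key), function(sub) {
    cbind(
      data.frame(image_id = sub$image_id[1], condition = sub$condition[1],
                 n_particles = nrow(sub), stringsAsFactors = FALSE),
      as.data.frame(as.list(colMeans(sub[, parameters, drop = FALSE])))
    )
  }))
  rownames(out) <- NULL
  out[order(out$condition, out$image_id), ]
}

#' Shapiro-Wilk normality screen
#'
#' Thin wrapper over the Royston algorithm (as implemented in
#' [stats::shapiro.test()]); used as an advisory screen before the
#' Gaussian group tests, never to switch tests automatically.
#'
#' @param values numeric vector, `3 <= n <= 5000`, non-constant.
#' @return A list with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(values) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (sd(values) == 0) stop("sample is constant: W is undefined")
  res <- shapiro.test(values)
  list(W = unname(res$statistic), p = res$p.value)
}

check_groups <- function(values, groups) {
  if (length(values) != length(groups)) stop("length mismatch")
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.character(groups[ok])
  n <- table(groups)
  if (length(n) < 2) stop("need at least two groups")
  if (any(n < 2)) stop("every group needs at least two observations")
  list(values = values, groups = groups)
}

#' One-way analysis of variance
#'
#' Classic between/within decomposition with the p-value from the F
#' distribution; group means and standard errors (SEM = SD/sqrt(n)) are
#' reported alongside.
#'
#' @param values numeric response vector.
#' @param groups condition label per observation.
#' @return A list of class `anova_result`: `F`, `df` (between, within),
#'   `p`, `ss_between`, `ss_within`, and `group_means` (data.frame with
#'   `condition`, `n`, `mean`, `sem`).
#' @export
one_way_anova <- function(values, groups) {
  g <- check_groups(values, groups)
  values <- g$values; groups <- g$groups
  k <- length(unique(groups))
  N <- length(values)
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  sds <- tapply(values, groups, sd)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  if (ssw <= 0)
    stop("zero within-group variance: the F statistic is undefined")
  df1 <- k - 1
  df2 <- N - k
  f <- (ssb / df1) / (ssw / df2)
  structure(list(
    F = f, df = c(between = df1, within = df2),
    p = pf(f, df1, df2, lower.tail = FALSE),
    ss_between = ssb, ss_within = ssw, ms_within = ssw / df2,
    group_means = data.frame(
      condition = names(means), n = as.integer(ns),
      mean = as.numeric(means), sem = as.numeric(sds / sqrt(ns)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  ), class = "anova_result")
}

# Correlation matrix of the treatment-vs-control t statistics induced by
# the shared control: rho_ij = sqrt(n_i n_j / ((n_i + n0)(n_j + n0))).
dunnett_corr <- function(n_treat, n_control) {
  w <- sqrt(n_treat / (n_treat + n_control))
  r <- outer(w, w)
  diag(r) <- 1
  r
}

#' Dunnett's many-to-one comparisons
#'
#' Compares every treatment group to a shared control using the pooled
#' within-group variance:
#' `t_i = (mean_i - mean_0) / sqrt(MSW * (1/n_i + 1/n_0))`.
#' Two-sided adjusted p-values come from the joint null distribution of
#' `max |T|`, where T is multivariate t with `N - k` degrees of freedom
#' and correlation induced by the shared control (0.5 for balanced
#' designs; the exact unbalanced form is used). Two evaluation methods
#' are available: seeded Monte Carlo over the multivariate t (default,
#' `mc_draws` draws) or quasi-deterministic numerical integration via
#' `mvtnorm::pmvt` (`method = "mvt"`).
#'
#' @param values numeric response vector.
#' @param groups condition label per observation.
#' @param control control group label.
#' @param alpha family-wise significance level.
#' @param method `"mc"` or `"mvt"`.
#' @param mc_draws Monte Carlo draws (>= 1e5 recommended).
#' @param seed RNG seed for the Monte Carlo evaluation (recorded in the
#'   output).
#' @return A data.frame of class `dunnett_result`: one row per treatment
#'   (`comparison`, `estimate`, `se`, `t`, `p_adj`, `significant`), with
#'   attributes `method`, `seed`, `df`, `alpha`.
#' @export
dunnett <- function(values, groups, control, alpha = 0.05,
                    method = c("mc", "mvt"), mc_draws = 1e5, seed = 1L) {
  method <- match.arg(method)
  g <- check_groups(values, groups)
  values <- g$values; groups <- g$groups
  if (!control %in% groups) stop("control group '", control, "' not found")
  labs <- unique(groups)
  treats <- setdiff(labs, control)
  if (length(treats) < 1) stop("need at least one treatment group")
  k <- length(labs)
  N <- length(values)
  nu <- N - k
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  msw <- sum((values - means[groups])^2) / nu
  if (msw <= 0) stop("zero within-group variance")
  n0 <- ns[[control]]
  nt <- vapply(treats, function(tr) ns[[tr]], numeric(1))
  se <- sqrt(msw * (1 / nt + 1 / n0))
  est <- vapply(treats, function(tr) means[[tr]] - means[[control]],
                numeric(1))
  tstat <- est / se
  R <- dunnett_corr(nt, n0)

  p_adj <- if (method == "mc") {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    U <- chol(R)
    Z <- matrix(rnorm(mc_draws * length(treats)), mc_draws) %*% U
    s <- sqrt(rchisq(mc_draws, nu) / nu)
    maxT <- apply(abs(Z / s), 1, max)
    vapply(abs(tstat), function(tt) mean(maxT >= tt), numeric(1))
  } else {
    if (!requireNamespace("mvtnorm", quietly = TRUE))
      stop("method 'mvt' requires the mvtnorm package")
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    vapply(abs(tstat), function(tt) {
      inside <- mvtnorm::pmvt(lower = rep(-tt, length(treats)),
                              upper = rep(tt, length(treats)),
                              df = as.integer(nu), corr = R,
                              type = "Kshirsagar")
      max(0, min(1, 1 - as.numeric(inside)))
    }, numeric(1))
  }

  out <- data.frame(
    comparison = paste(treats, "vs", control),
    treatment = treats,
    estimate = est, se = se, t = tstat, p_adj = p_adj,
    significant = p_adj < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "method") <- method
  attr(out, "seed") <- seed
  attr(out, "df") <- nu
  attr(out, "alpha") <- alpha
  class(out) <- c("dunnett_result", "data.frame")
  out
}

#' Fisher's least-significant-difference comparisons
#'
#' Unadjusted pairwise t-tests of each treatment against the control using
#' the pooled within-group variance (the ANOVA error term) with `N - k`
#' degrees of freedom. No multiplicity adjustment: the per-comparison
#' error rate, not the family-wise rate, is held at `alpha`.
#'
#' @inheritParams dunnett
#' @return A data.frame: `comparison`, `estimate`, `se`, `t`, `p`,
#'   `significant`.
#' @export
fisher_lsd <- function(values, groups, control, alpha = 0.05) {
  g <- check_groups(values, groups)
  values <- g$values; groups <- g$groups
  if (!control %in% groups) stop("control group '", control, "' not found")
  labs <- unique(groups)
  treats <- setdiff(labs, control)
  if (length(treats) < 1) stop("need at least one treatment group")
  k <- length(labs)
  nu <- length(values) - k
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  msw <- sum((values - means[groups])^2) / nu
  n0 <- ns[[control]]
  nt <- vapply(treats, function(tr) ns[[tr]], numeric(1))
  se <- sqrt(msw * (1 / nt + 1 / n0))
  est <- vapply(treats, function(tr) means[[tr]] - means[[control]],
                numeric(1))
  tstat <- est / se
  p <- 2 * pt(abs(tstat), nu, lower.tail = FALSE)
  data.frame(
    comparison = paste(treats, "vs", control),
    treatment = treats,
    estimate = est, se = se, t = tstat, p = p,
    significant = p < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Group analysis of per-cell summaries
#'
#' For each morphological parameter: Shapiro-Wilk normality screen per
#' condition (advisory, logged, never switches the test), one-way ANOVA
#' across conditions, and Dunnett's many-to-one comparisons against the
#' control.
#'
#' @param cells per-cell summary data.frame from [aggregate_per_cell()].
#' @param control control condition label.
#' @param alpha significance level.
#' @param parameters parameter columns to analyze.
#' @param method,mc_draws,seed passed to [dunnett()].
#' @return A list of class `group_analysis`: `anova` (one row per
#'   parameter), `dunnett` (one row per parameter x comparison), `means`
#'   (parameter x condition means with SEM), `normality` (Shapiro-Wilk W
#'   and p per parameter x condition).
#' @export
run_group_analysis <- function(cells, control, alpha = 0.05,
                               parameters = MORPHO_PARAMETERS,
                               method = c("mc", "mvt"),
                               mc_draws = 1e5, seed = 1L) {
  method <- match.arg(method)
  if (!control %in% cells$condition)
    stop("control condition '", control, "' not present")
  if (length(unique(cells$condition)) < 2)
    stop("need at least two conditions")
  parameters <- intersect(parameters, names(cells))
  if (length(parameters) == 0) stop("no parameter columns found")

  anova_rows <- list(); dunnett_rows <- list()
  means_rows <- list(); norm_rows <- list()
  for (pm in parameters) {
    v <- cells[[pm]]
    for (cond in unique(cells$condition)) {
      w <- tryCatch(shapiro_wilk(v[cells$condition == cond]),
                    error = function(e) list(W = NA_real_, p = NA_real_))
      norm_rows[[length(norm_rows) + 1L]] <- data.frame(
        parameter = pm, condition = cond, W = w$W, p = w$p,
        stringsAsFactors = FALSE
      )
    }
    an <- one_way_anova(v, cells$condition)
    anova_rows[[length(anova_rows) + 1L]] <- data.frame(
      parameter = pm, F = an$F, df_between = an$df[["between"]],
      df_within = an$df[["within"]], p = an$p, stringsAsFactors = FALSE
    )
    means_rows[[length(means_rows) + 1L]] <-
      cbind(parameter = pm, an$group_means)
    dn <- dunnett(v, cells$condition, control, alpha = alpha,
                  method = method, mc_draws = mc_draws, seed = seed)
    dunnett_rows[[length(dunnett_rows) + 1L]] <-
      cbind(parameter = pm, as.data.frame(dn))
  }
  structure(list(
    anova = do.call(rbind, anova_rows),
    dunnett = do.call(rbind, dunnett_rows),
    means = do.call(rbind, means_rows),
    normality = do.call(rbind, norm_rows),
    control = control, alpha = alpha,
    dunnett_method = method, seed = seed
  ), class = "group_analysis")
}

#' @export
print.group_analysis <- function(x, ...) {
  cat("Group analysis (control:", x$control, "; alpha =", x$alpha, ")\n")
  cat("\nOne-way ANOVA per parameter:\n")
  print(x$anova, ...)
  cat("\nDunnett comparisons:\n")
  print(x$dunnett, ...)
  invisible(x)
}
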