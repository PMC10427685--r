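#' Quality-control a Ct triplicate
#'
#' Applies the triplicate reproducibility rule: if the sample standard
#' deviation of the three Ct values is at most `sd_limit` cycles, all
#' replicates are kept. Otherwise the single replicate whose removal
#' minimizes the remaining pair's SD is dropped; if that pair still
#' exceeds the limit, the whole triplicate is excluded (exclusion is a
#' state, not an error). This is the most conservative reading of an
#' "SD > 0.5 removes outliers" rule that always keeps at least two
#' replicates.
#'
#' @param ct numeric vector of exactly three Ct values (cycles).
#' @param sd_limit SD limit in cycles (default 0.5).
#' @return A list: `kept` (retained Ct values, `numeric(0)` if excluded),
#'   `removed` (dropped value or `NULL`), `excluded` (logical),
#'   `sd_before`, `sd_after`.
#' @export
qc_triplicate <- function(ct, sd_limit = 0.5) {
  if (length(ct) != 3 || anyNA(ct)) stop("a complete triplicate is required")
  s0 <- sd(ct)
  if (s0 <= sd_limit) {
    return(list(kept = ct, removed = NULL, excluded = FALSE,
                sd_before = s0, sd_after = s0))
  }
  pair_sd <- vapply(1:3, function(i) sd(ct[-i]), numeric(1))
  drop <- which.min(pair_sd)
  if (pair_sd[drop] <= sd_limit) {
    list(kept = ct[-drop], removed = ct[drop], excluded = FALSE,
         sd_before = s0, sd_after = pair_sd[drop])
  } else {
    list(kept = numeric(0), removed = NULL, excluded = TRUE,
         sd_before = s0, sd_after = pair_sd[drop])
  }
}

#' Quality-control a long-format Ct table
#'
#' Applies [qc_triplicate()] to every (gene, sample) triplicate and
#' returns the cleaned table together with an audit log recording every
#' removal and exclusion with the computed SDs.
#'
#' @param ct long-format data.frame with columns `gene`, `sample`,
#'   `condition`, `replicate`, `ct`.
#' @param sd_limit SD limit in cycles.
#' @return A list: `ct` (cleaned table, excluded triplicates dropped) and
#'   `log` (one row per triplicate: SDs, action taken).
#' @export
qc_ct_table <- function(ct, sd_limit = 0.5) {
  need <- c("gene", "sample", "condition", "replicate", "ct")
  if (!all(need %in% names(ct)))
    stop("Ct table needs columns ", paste(need, collapse = ", "))
  key <- interaction(ct$gene, ct$sample, drop = TRUE)
  kept_rows <- list()
  logs <- list()
  i <- 0L
  for (k in levels(key)) {
    sub <- ct[key == k, , drop = FALSE]
    if (nrow(sub) != 3)
      stop("triplicate expected for ", k, ", found ", nrow(sub), " rows")
    qc <- qc_triplicate(sub$ct, sd_limit)
    i <- i + 1L
    logs[[i]] <- data.frame(
      gene = sub$gene[1], sample = sub$sample[1],
      condition = sub$condition[1],
      sd_before = qc$sd_before, sd_after = qc$sd_after,
      action = if (qc$excluded) "excluded"
               else if (is.null(qc$removed)) "kept_all"
               else "removed_one",
      removed_ct = if (is.null(qc$removed)) NA_real_ else qc$removed,
      stringsAsFactors = FALSE
    )
    if (!qc$excluded) {
      keep_idx <- if (is.null(qc$removed)) 1:3 else which(sub$ct %in% qc$kept)
      # guard against duplicated values: keep exactly the retained count
      keep_idx <- keep_idx[seq_along(qc$kept)]
      kept_rows[[length(kept_rows) + 1L]] <- sub[keep_idx, , drop = FALSE]
    }
  }
  list(ct = do.call(rbind, kept_rows), log = do.call(rbind, logs))
}

#' Relative expression by the 2^-ddCt method
#'
#' For every biological sample, the delta-Ct is the mean Ct of the target
#' gene minus the mean Ct of the reference gene (after triplicate QC).
#' The delta-delta-Ct of a treated sample is its delta-Ct minus the mean
#' control delta-Ct for that gene, and the per-sample fold change is
#' `2^-ddCt`. Fold changes are summarized per gene and condition as
#' `2^-mean(ddCt)` (the geometric mean of per-sample fold changes).
#' Samples whose target or reference triplicate was excluded by QC are
#' flagged missing and dropped from the summary.
#'
#' @param ct long-format Ct table (see [qc_ct_table()]); QC is applied
#'   internally with `sd_limit`.
#' @param reference_gene reference gene name (must be present).
#' @param control_condition control condition label.
#' @param sd_limit triplicate QC limit in cycles.
#' @return A list of class `ddct_result`: `fold_changes` (per gene and
#'   condition: mean ddCt, fold change, samples used), `per_sample`
#'   (per-sample detail), `qc_log`.
#' @export
ddct_fold_change <- function(ct, reference_gene = "B2M",
                             control_condition = "control",
                             sd_limit = 0.5) {
  qc <- qc_ct_table(ct, sd_limit)
  cleaned <- qc$ct
  if (!reference_gene %in% cleaned$gene)
    stop("reference gene '", reference_gene, "' not present after QC")
  if (!control_condition %in% cleaned$condition)
    stop("control condition '", control_condition, "' not present")

  mean_ct <- aggregate(ct ~ gene + sample + condition, cleaned, mean)
  nrep <- aggregate(ct ~ gene + sample + condition, cleaned, length)
  names(nrep)[4] <- "replicates_used"
  mean_ct <- merge(mean_ct, nrep, by = c("gene", "sample", "condition"))

  ref <- mean_ct[mean_ct$gene == reference_gene,
                 c("sample", "condition", "ct")]
  names(ref)[3] <- "ref_ct"
  targets <- mean_ct[mean_ct$gene != reference_gene, ]
  per_sample <- merge(targets, ref, by = c("sample", "condition"))
  per_sample$dct <- per_sample$ct - per_sample$ref_ct

  # control baseline per gene
  ctrl <- per_sample[per_sample$condition == control_condition, ]
  base <- aggregate(dct ~ gene, ctrl, mean)
  names(base)[2] <- "control_dct"
  per_sample <- merge(per_sample, base, by = "gene", all.x = TRUE)
  per_sample$ddct <- per_sample$dct - per_sample$control_dct
  per_sample$fold_change <- 2^(-per_sample$ddct)

  # samples lost to QC exclusions (target or reference missing)
  all_genes <- setdiff(unique(ct$gene), reference_gene)
  full <- unique(ct[, c("sample", "condition")])
  expected <- merge(data.frame(gene = all_genes), full)
  missing <- merge(expected, per_sample[, c("gene", "sample")],
                   by = c("gene", "sample"), all.x = TRUE,
                   suffixes = c("", ".y"))
  missing <- expected[!paste(expected$gene, expected$sample) %in%
                        paste(per_sample$gene, per_sample$sample), ]

  summ <- aggregate(ddct ~ gene + condition, per_sample, mean)
  nsum <- aggregate(ddct ~ gene + condition, per_sample, length)
  names(summ)[3] <- "mean_ddct"
  names(nsum)[3] <- "n_samples"
  summ <- merge(summ, nsum, by = c("gene", "condition"))
  summ$fold_change <- 2^(-summ$mean_ddct)
  summ <- summ[order(summ$gene, summ$condition), ]
  rownames(summ) <- NULL

  structure(list(
    fold_changes = summ,
    per_sample = per_sample,
    missing = missing,
    qc_log = qc$log,
    reference_gene = reference_gene,
    control_condition = control_condition
  ), class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat("2^-ddCt relative expression (reference:", x$reference_gene,
      "; control:", x$control_condition, ")\n")
  print(x$fold_changes, ...)
  n_removed <- sum(x$qc_log$action == "removed_one")
  n_excluded <- sum(x$qc_log$action == "excluded")
  cat(sprintf("QC: %d replicate(s) removed, %d triplicate(s) excluded\n",
              n_removed, n_excluded))
  invisible(x)
}
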