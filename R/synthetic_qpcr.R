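#' Specify a synthetic qPCR Ct table
#'
#' Describes triplicate Ct measurements for a set of target genes and a
#' reference gene across conditions, with known true expression
#' differences, so that the relative-quantification module can be
#' validated against generator truth.
#'
#' `true_dct` holds, per gene and condition, the true mean difference
#' between the target's Ct and the reference gene's Ct (cycles). The true
#' fold change of a gene in a treated condition relative to control is
#' then `2^-(dct_treated - dct_control)`.
#'
#' @param genes character vector of target gene names.
#' @param reference_gene reference (housekeeping) gene name.
#' @param conditions condition labels, control first.
#' @param n_samples biological samples per condition.
#' @param true_dct numeric matrix `genes x conditions` of true delta-Ct
#'   values (cycles).
#' @param ref_ct mean Ct of the reference gene (cycles).
#' @param noise_sd replicate noise SD (cycles).
#' @param outlier_rate probability that a triplicate contains one
#'   displaced replicate.
#' @param outlier_magnitude displacement in cycles (added to one
#'   replicate).
#' @param seed RNG seed.
#' @return An object of class `ct_table_spec`.
#' @export
ct_table_spec <- function(genes = c("STOML2", "NRF1", "TFAM", "OPA1"),
                          reference_gene = "B2M",
                          conditions = c("control", "treated"),
                          n_samples = 3,
                          true_dct = NULL,
                          ref_ct = 18,
                          noise_sd = 0.1,
                          outlier_rate = 0,
                          outlier_magnitude = 2,
                          seed = 1L) {
  if (is.null(true_dct)) {
    true_dct <- matrix(4, length(genes), length(conditions),
                       dimnames = list(genes, conditions))
  }
  true_dct <- as.matrix(true_dct)
  if (!all(dim(true_dct) == c(length(genes), length(conditions))))
    stop("'true_dct' must be a genes x conditions matrix")
  dimnames(true_dct) <- list(genes, conditions)
  if (reference_gene %in% genes)
    stop("the reference gene cannot also be a target gene")
  if (n_samples < 1) stop("need at least one sample per condition")
  if (outlier_rate < 0 || outlier_rate > 1)
    stop("'outlier_rate' must be in [0, 1]")
  structure(list(
    genes = genes, reference_gene = reference_gene,
    conditions = conditions, n_samples = as.integer(n_samples),
    true_dct = true_dct, ref_ct = ref_ct, noise_sd = noise_sd,
    outlier_rate = outlier_rate, outlier_magnitude = outlier_magnitude,
    seed = as.integer(seed)
  ), class = "ct_table_spec")
}

#' Generate a synthetic Ct table
#'
#' Draws triplicate Ct values per gene (targets plus reference), sample
#' and condition around the specified means, optionally injecting exactly
#' one displaced replicate per affected triplicate. Fixed seeds give
#' identical tables.
#'
#' @param spec a [ct_table_spec()].
#' @return A list with `ct` (long-format data.frame: `gene`, `sample`,
#'   `condition`, `replicate`, `ct`) and `truth` (data.frame of true fold
#'   changes per gene and non-control condition, `2^-(true ddCt)`).
#' @export
generate_ct_table <- function(spec) {
  stopifnot(inherits(spec, "ct_table_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(spec$seed)
  all_genes <- c(spec$genes, spec$reference_gene)
  rows <- list()
  k <- 0L
  for (cond in spec$conditions) {
    for (s in seq_len(spec$n_samples)) {
      sample_id <- sprintf("%s_s%d", cond, s)
      for (g in all_genes) {
        mu <- if (g == spec$reference_gene) spec$ref_ct
              else spec$ref_ct + spec$true_dct[g, cond]
        ct <- mu + rnorm(3, 0, spec$noise_sd)
        if (spec$outlier_rate > 0 && runif(1) < spec$outlier_rate) {
          hit <- sample.int(3, 1)
          ct[hit] <- ct[hit] + spec$outlier_magnitude
        }
        k <- k + 1L
        rows[[k]] <- data.frame(
          gene = g, sample = sample_id, condition = cond,
          replicate = 1:3, ct = ct, stringsAsFactors = FALSE
        )
      }
    }
  }
  ct <- do.call(rbind, rows)
  control <- spec$conditions[1]
  treated <- setdiff(spec$conditions, control)
  truth <- do.call(rbind, lapply(treated, function(cond) {
    data.frame(
      gene = spec$genes, condition = cond,
      true_ddct = spec$true_dct[spec$genes, cond] -
        spec$true_dct[spec$genes, control],
      stringsAsFactors = FALSE
    )
  }))
  truth$true_fold_change <- 2^(-truth$true_ddct)
  list(ct = ct, truth = truth)
}
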