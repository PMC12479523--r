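#' Run the full mimicry screen on aligned multi-omics inputs
#'
#' Convenience wrapper chaining the pipeline stages: align all matrices (and
#' the covariate table) on their shared samples, correlate taxa against
#' expression with ordinary Spearman and metabolites against expression with
#' partial Spearman given the named covariates (Lactobacillus dominance by
#' default), cut per-feature up/down gene signatures at `alpha`, and run the
#' directional Fisher screen against the drug catalog.
#'
#' @param expression [omics_matrix] of host expression.
#' @param taxa optional [omics_matrix] of taxon abundances.
#' @param metabolites optional [omics_matrix] of metabolite intensities.
#' @param covariates optional [covariate_table]; required when
#'   `covariate_names` is non-empty and metabolites are supplied.
#' @param drug_sigs list of [drug_signature] objects.
#' @param alpha adjusted-p threshold for signature extraction (default 0.05).
#' @param covariate_names covariates controlling metabolite-gene correlations
#'   (default `"lactobacillus_dominance"`).
#' @param screen a [screen_config].
#' @param min_pairs minimum complete pairs per correlation record.
#' @return list with `correlations` (per input kind), `signatures` (named
#'   list of [gene_signature]), and `screen` (the [run_screen] result table).
#' @export
pharmacobiome_screen <- function(expression, taxa = NULL, metabolites = NULL,
                                 covariates = NULL, drug_sigs,
                                 alpha = 0.05,
                                 covariate_names = "lactobacillus_dominance",
                                 screen = screen_config(),
                                 min_pairs = 5L) {
  if (is.null(taxa) && is.null(metabolites)) {
    stop("supply at least one of `taxa` or `metabolites`", call. = FALSE)
  }
  mats <- list(expression = expression)
  if (!is.null(taxa)) mats$taxa <- taxa
  if (!is.null(metabolites)) mats$metabolites <- metabolites
  al <- align_samples(mats, covariates = covariates)
  expression <- al$matrices$expression
  universe <- colnames(expression$values)

  correlations <- list()
  sigs <- list()
  if (!is.null(taxa)) {
    cfg <- correlation_config(alpha = alpha, min_pairs = min_pairs)
    correlations$taxa <- correlate_features(al$matrices$taxa, expression, config = cfg)
    sigs <- c(sigs, extract_signatures(correlations$taxa, universe, alpha))
  }
  if (!is.null(metabolites)) {
    use_cov <- length(covariate_names) > 0 && !is.null(al$covariates)
    cfg <- correlation_config(alpha = alpha, min_pairs = min_pairs,
                              covariate_names = if (use_cov) covariate_names else character(0))
    correlations$metabolites <- correlate_features(
      al$matrices$metabolites, expression,
      covariates = al$covariates, config = cfg)
    sigs <- c(sigs, extract_signatures(correlations$metabolites, universe, alpha))
  }

  results <- run_screen(sigs, drug_sigs, screen)
  list(correlations = correlations, signatures = sigs, screen = results)
}
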