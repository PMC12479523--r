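default_taxon_names <- function(n) {
  named <- c("Lactobacillus", "Lactobacillus_crispatus", "Lactobacillus_iners",
             "Gardnerella_vaginalis", "Prevotella_bivia")
  c(named[seq_len(min(n, length(named)))],
    if (n > length(named)) sprintf("taxon_%03d", seq.int(length(named) + 1L, n)))
}

default_metabolite_names <- function(n) {
  named <- c("taurine", "cytosine", "glutathione", "pyruvate", "tyramine")
  c(named[seq_len(min(n, length(named)))],
    if (n > length(named)) sprintf("metabolite_%03d", seq.int(length(named) + 1L, n)))
}

default_class_names <- c("antiestrogen", "aromatase_inhibitor",
                         "topoisomerase_inhibitor", "mtor_inhibitor",
                         "protein_kinase_inhibitor", "antimetabolite",
                         "alkylating_agent")

#' Configuration of the synthetic multi-omics cohort generator
#'
#' Defines a cohort with known planted structure: a binary
#' Lactobacillus-dominance covariate, logistic-normal taxon abundances with
#' one dominance-tied taxon, lognormal metabolite intensities, and host
#' expression in which selected (feature, gene) pairs carry planted monotone
#' effects. A configurable fraction of metabolite effects is confounded: the
#' dominance covariate drives both the metabolite and its genes with no
#' direct link, the design that separates partial from ordinary Spearman.
#' Drugs are generated in mechanism classes sharing a planted core gene set,
#' and mimicry pairs plant directional overlap between a feature's gene
#' signature and a specific drug's sets.
#'
#' The default dimensions emulate a vaginal-microbiome multi-omics cohort
#' (90 samples, 51 taxa, 99 metabolites, 35 drugs in 7 mechanism classes) at
#' a reduced gene count of 2000 for tractable simulation; pass a larger
#' `n_genes` for full-scale generation. Default planted structure: 4 taxa and
#' 5 metabolites each carry 75 up and 75 down planted genes at effect size
#' 1.5 against unit noise, 2 of the 5 metabolites confounded; each drug class
#' is anchored to one non-confounded planted feature through its class core,
#' and one drug per class is a planted mimic of that feature.
#'
#' @param n_samples,n_genes,n_taxa,n_metabolites,n_drugs cohort dimensions.
#' @param planted_taxon_effects data.frame(`feature_id`, `n_genes`, `effect`,
#'   `sign`) or `NULL` for the default; an empty data.frame plants nothing.
#' @param planted_metabolite_effects same shape plus a logical `confounded`
#'   column; `NULL` for the default derived from `confounded_fraction`.
#' @param confounded_fraction fraction of default planted metabolites that
#'   are confounded by the dominance covariate (default 0.3).
#' @param mimicry_pairs data.frame(`feature_id`, `drug_id`, `fraction`) or
#'   `NULL` for the default (one mimicking drug per anchored class at
#'   `mimicry_overlap`).
#' @param drug_classes data.frame(`drug_id`, `class`) or `NULL` for the
#'   default 7-class partition.
#' @param effect_size planted effect size relative to `noise_sd` (default 1.5).
#' @param genes_per_direction planted genes per sign per feature (default 75).
#' @param noise_sd expression noise standard deviation (default 1).
#' @param drug_set_size genes per drug per direction (default 200).
#' @param class_core_size genes of the shared class core per direction
#'   (default 150; the remainder is drug-private noise).
#' @param class_core_overlap fraction of an anchor feature's planted set
#'   included in its class core (default 0.5).
#' @param mimicry_overlap default overlap fraction for generated mimicry
#'   pairs (default 0.5).
#' @param dominance_effect shift of the dominance-tied taxon's latent
#'   abundance (default 2).
#' @param seed integer seed; mandatory, all randomness derives from it.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_samples = 90L, n_genes = 2000L, n_taxa = 51L,
                             n_metabolites = 99L, n_drugs = 35L,
                             planted_taxon_effects = NULL,
                             planted_metabolite_effects = NULL,
                             confounded_fraction = 0.3,
                             mimicry_pairs = NULL,
                             drug_classes = NULL,
                             effect_size = 1.5,
                             genes_per_direction = 75L,
                             noise_sd = 1,
                             drug_set_size = 200L,
                             class_core_size = 150L,
                             class_core_overlap = 0.5,
                             mimicry_overlap = 0.5,
                             dominance_effect = 2,
                             seed) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is mandatory: the generator never runs nondeterministically", call. = FALSE)
  }
  stopifnot(n_samples >= 1, n_genes >= 1, n_taxa >= 1, n_metabolites >= 1,
            n_drugs >= 1, noise_sd > 0, mimicry_overlap > 0, mimicry_overlap <= 1,
            class_core_overlap >= 0, class_core_overlap <= 1,
            confounded_fraction >= 0, confounded_fraction <= 1,
            drug_set_size >= class_core_size)
  taxa_ids <- default_taxon_names(n_taxa)
  met_ids <- default_metabolite_names(n_metabolites)

  if (is.null(planted_taxon_effects)) {
    anchors_t <- taxa_ids[seq.int(2L, min(5L, n_taxa))]   # dominance-tied taxon excluded
    planted_taxon_effects <- data.frame(
      feature_id = rep(anchors_t, each = 2L),
      n_genes = genes_per_direction,
      effect = effect_size,
      sign = rep(c(1, -1), length(anchors_t)),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(planted_metabolite_effects)) {
    anchors_m <- met_ids[seq_len(min(5L, n_metabolites))]
    n_conf <- round(confounded_fraction * length(anchors_m))
    conf <- rep(FALSE, length(anchors_m))
    if (n_conf > 0) conf[seq.int(length(anchors_m) - n_conf + 1L, length(anchors_m))] <- TRUE
    planted_metabolite_effects <- data.frame(
      feature_id = rep(anchors_m, each = 2L),
      n_genes = genes_per_direction,
      effect = effect_size,
      sign = rep(c(1, -1), length(anchors_m)),
      confounded = rep(conf, each = 2L),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(planted_metabolite_effects) && !"confounded" %in% names(planted_metabolite_effects)) {
    planted_metabolite_effects$confounded <- FALSE
  }

  if (is.null(drug_classes)) {
    n_classes <- min(length(default_class_names), n_drugs)
    cls <- rep(default_class_names[seq_len(n_classes)], length.out = n_drugs)
    cls <- sort(cls)
    counts <- table(cls)
    drug_id <- unlist(lapply(names(counts), function(cl) {
      sprintf("%s_%d", cl, seq_len(counts[[cl]]))
    }), use.names = FALSE)
    drug_classes <- data.frame(drug_id = drug_id, class = sort(cls),
                               stringsAsFactors = FALSE)
  }
  if (nrow(drug_classes) != n_drugs) {
    stop("drug_classes must assign a class to every drug", call. = FALSE)
  }

  if (is.null(mimicry_pairs)) {
    planted_feats <- c(unique(planted_taxon_effects$feature_id),
                       unique(planted_metabolite_effects$feature_id[
                         !planted_metabolite_effects$confounded]))
    classes <- unique(drug_classes$class)
    n_pairs <- min(length(planted_feats), length(classes))
    if (n_pairs > 0L) {
      first_drug <- vapply(classes[seq_len(n_pairs)], function(cl) {
        drug_classes$drug_id[drug_classes$class == cl][1L]
      }, character(1))
      mimicry_pairs <- data.frame(feature_id = planted_feats[seq_len(n_pairs)],
                                  drug_id = unname(first_drug),
                                  fraction = mimicry_overlap,
                                  stringsAsFactors = FALSE)
    } else {
      mimicry_pairs <- data.frame(feature_id = character(0), drug_id = character(0),
                                  fraction = numeric(0), stringsAsFactors = FALSE)
    }
  }
  if (nrow(mimicry_pairs) && (any(mimicry_pairs$fraction <= 0) || any(mimicry_pairs$fraction > 1))) {
    stop("mimicry overlap fractions must lie in (0, 1]", call. = FALSE)
  }

  demand <- sum(planted_taxon_effects$n_genes) + sum(planted_metabolite_effects$n_genes)
  if (demand > n_genes) {
    stop(sprintf("planted effects demand %d genes but n_genes = %d", demand, n_genes),
         call. = FALSE)
  }

  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    n_taxa = as.integer(n_taxa), n_metabolites = as.integer(n_metabolites),
    n_drugs = as.integer(n_drugs),
    planted_taxon_effects = planted_taxon_effects,
    planted_metabolite_effects = planted_metabolite_effects,
    confounded_fraction = confounded_fraction,
    mimicry_pairs = mimicry_pairs, drug_classes = drug_classes,
    effect_size = effect_size, genes_per_direction = as.integer(genes_per_direction),
    noise_sd = noise_sd, drug_set_size = as.integer(drug_set_size),
    class_core_size = as.integer(class_core_size),
    class_core_overlap = class_core_overlap, mimicry_overlap = mimicry_overlap,
    dominance_effect = dominance_effect, seed = as.integer(seed),
    taxa_ids = taxa_ids, metabolite_ids = met_ids,
    gene_ids = sprintf("GENE%05d", seq_len(n_genes)),
    sample_ids = sprintf("S%03d", seq_len(n_samples))
  ), class = "generator_config")
}

monotone_links <- list(
  identity = function(x) x,
  sqrt = function(x) sqrt(pmax(x, 0)),
  log = function(x) log(pmax(x, 0) + 1e-8)
)

scale_unit <- function(x) {
  s <- stats::sd(x)
  if (s < 1e-12) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Generate a synthetic multi-omics cohort with known truth
#'
#' Latent-factor construction: a Bernoulli(0.5) dominance covariate per
#' sample; taxon abundances as softmax-normalized (logistic-normal) latent
#' Gaussians with the first taxon's latent mean shifted by the dominance
#' state; lognormal metabolite intensities; host expression as per-gene
#' baseline plus unit-variance monotone transforms of the planted driver
#' scaled by the effect size, plus Gaussian noise. Monotone links are drawn
#' per planted record from identity, square-root and log so the design does
#' not secretly favor linear (Pearson-equivalent) settings. Confounded
#' metabolite records route the dominance covariate into both the metabolite
#' and its genes with no direct link. Fully reproducible from the config
#' seed; per-matrix sub-streams are derived deterministically from it.
#'
#' @param config a [generator_config].
#' @return list with `expression`, `taxa`, `metabolites` ([omics_matrix]
#'   objects), `covariates` ([covariate_table] with `lactobacillus_dominance`),
#'   and `truth` (planted-effect records, dominance vector, mimicry pairs,
#'   drug classes, and the sub-seed consumed by [generate_drug_catalog]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  sub <- sample.int(2147483646L, 6L)
  n <- config$n_samples

  set.seed(sub[1L])
  dominance <- stats::rbinom(n, 1L, 0.5)

  # taxa: logistic-normal with dominance-tied first taxon
  set.seed(sub[2L])
  latent <- matrix(stats::rnorm(n * config$n_taxa), n, config$n_taxa)
  latent <- sweep(latent, 2L, stats::rnorm(config$n_taxa, 0, 0.5), `+`)
  latent[, 1L] <- latent[, 1L] + config$dominance_effect * (2 * dominance - 1)
  expl <- exp(latent)
  taxa_vals <- expl / rowSums(expl)
  dimnames(taxa_vals) <- list(config$sample_ids, config$taxa_ids)

  # metabolites: lognormal baseline; confounded columns driven by dominance
  set.seed(sub[3L])
  met_log <- matrix(stats::rnorm(n * config$n_metabolites), n, config$n_metabolites)
  dimnames(met_log) <- list(config$sample_ids, config$metabolite_ids)
  conf_mets <- unique(config$planted_metabolite_effects$feature_id[
    config$planted_metabolite_effects$confounded])
  for (m in conf_mets) {
    met_log[, m] <- config$effect_size * dominance + stats::rnorm(n)
  }
  met_vals <- exp(met_log)

  # expression baseline
  set.seed(sub[4L])
  expr <- matrix(stats::rnorm(n * config$n_genes, 0, config$noise_sd), n, config$n_genes)
  expr <- sweep(expr, 2L, stats::runif(config$n_genes, 6, 12), `+`)
  dimnames(expr) <- list(config$sample_ids, config$gene_ids)

  # planted effects: sequential gene-block allocation, links drawn per record
  set.seed(sub[5L])
  entries <- rbind(
    if (nrow(config$planted_taxon_effects)) {
      cbind(config$planted_taxon_effects[, c("feature_id", "n_genes", "effect", "sign")],
            kind = "taxon", confounded = FALSE)
    },
    if (nrow(config$planted_metabolite_effects)) {
      cbind(config$planted_metabolite_effects[, c("feature_id", "n_genes", "effect", "sign")],
            kind = "metabolite",
            confounded = config$planted_metabolite_effects$confounded)
    }
  )
  truth_rows <- list()
  next_gene <- 1L
  if (!is.null(entries) && nrow(entries)) {
    for (i in seq_len(nrow(entries))) {
      e <- entries[i, ]
      block <- config$gene_ids[seq.int(next_gene, next_gene + e$n_genes - 1L)]
      next_gene <- next_gene + e$n_genes
      link_name <- sample(names(monotone_links), 1L)
      driver <- if (e$confounded) {
        as.numeric(dominance)        # no direct feature-gene link
      } else if (e$kind == "taxon") {
        taxa_vals[, e$feature_id]
      } else {
        met_vals[, e$feature_id]
      }
      z <- scale_unit(monotone_links[[link_name]](driver))
      expr[, block] <- expr[, block] + e$sign * e$effect * z
      truth_rows[[i]] <- data.frame(
        feature_id = e$feature_id, feature_kind = e$kind, gene_id = block,
        sign = e$sign, effect = e$effect, confounded = e$confounded,
        link = if (e$confounded) "dominance" else link_name,
        stringsAsFactors = FALSE)
    }
  }
  planted <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(feature_id = character(0), feature_kind = character(0),
               gene_id = character(0), sign = numeric(0), effect = numeric(0),
               confounded = logical(0), link = character(0), stringsAsFactors = FALSE)
  rownames(planted) <- NULL

  covs <- covariate_table(config$sample_ids, lactobacillus_dominance = dominance)
  truth <- structure(list(
    planted_effects = planted,
    dominance = stats::setNames(dominance, config$sample_ids),
    mimicry_pairs = config$mimicry_pairs,
    drug_classes = config$drug_classes,
    gene_ids = config$gene_ids,
    catalog_seed = sub[6L]
  ), class = "synthetic_truth")

  list(expression = omics_matrix(expr, "expression"),
       taxa = omics_matrix(taxa_vals, "taxa"),
       metabolites = omics_matrix(met_vals, "metabolite"),
       covariates = covs,
       truth = truth)
}

truth_feature_set <- function(truth, feature, direction) {
  pe <- truth$planted_effects
  sel <- pe$feature_id == feature & (if (direction == "up") pe$sign > 0 else pe$sign < 0)
  pe$gene_id[sel]
}

#' Generate a drug catalog with class structure and planted mimicry
#'
#' Drugs in the same mechanism class share a class-core gene set per
#' direction plus drug-private noise genes. Each class whose drugs appear in
#' a mimicry pair is anchored to that pair's feature: the class core includes
#' `class_core_overlap` of the feature's planted up/down genes, which is what
#' makes mechanism classes recoverable from the similarity matrix. For each
#' mimicry pair the drug's sets additionally receive an independently drawn
#' `fraction` of the feature's planted genes, so the mimicking drug overlaps
#' its feature more strongly than its classmates. Metadata is stamped with
#' the default cell line, dose and timepoint so catalog filters pass.
#'
#' @param config the [generator_config] used for the cohort.
#' @param truth the `truth` element returned by [generate_cohort].
#' @return list with `signatures` (named list of [drug_signature]) and
#'   `metadata` (data.frame sidecar).
#' @export
generate_drug_catalog <- function(config, truth) {
  stopifnot(inherits(config, "generator_config"), inherits(truth, "synthetic_truth"))
  set.seed(truth$catalog_seed)
  genes <- truth$gene_ids
  classes_df <- truth$drug_classes
  pairs <- truth$mimicry_pairs

  if (nrow(pairs)) {
    has_effect <- pairs$feature_id %in% truth$planted_effects$feature_id
    if (any(!has_effect)) {
      stop("mimicry pair references effect-free feature(s): ",
           paste(pairs$feature_id[!has_effect], collapse = ", "), call. = FALSE)
    }
    unknown <- setdiff(pairs$drug_id, classes_df$drug_id)
    if (length(unknown)) {
      stop("mimicry pair references unknown drug(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }

  # anchor each class to the feature of its first mimicry pair, if any
  anchor <- list()
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      cl <- classes_df$class[classes_df$drug_id == pairs$drug_id[i]]
      if (is.null(anchor[[cl]])) anchor[[cl]] <- pairs$feature_id[i]
    }
  }

  structured <- unique(c(truth$planted_effects$gene_id))
  free_pool <- setdiff(genes, structured)
  if (length(free_pool) < 2L * config$drug_set_size) {
    stop(sprintf(paste0("only %d genes remain outside planted sets but drug ",
                        "construction needs at least %d; increase n_genes"),
                 length(free_pool), 2L * config$drug_set_size), call. = FALSE)
  }

  # cores of different classes may share filler genes: fillers never touch
  # planted sets, so they cannot create spurious feature-drug overlap
  cores <- list()
  for (cl in unique(classes_df$class)) {
    f <- anchor[[cl]]
    take_up <- take_dn <- character(0)
    if (!is.null(f)) {
      f_up <- truth_feature_set(truth, f, "up")
      f_dn <- truth_feature_set(truth, f, "down")
      if (length(f_up)) take_up <- sample(f_up, round(config$class_core_overlap * length(f_up)))
      if (length(f_dn)) take_dn <- sample(f_dn, round(config$class_core_overlap * length(f_dn)))
    }
    fill_up <- sample(free_pool, max(0L, config$class_core_size - length(take_up)))
    fill_dn <- sample(setdiff(free_pool, fill_up),
                      max(0L, config$class_core_size - length(take_dn)))
    cores[[cl]] <- list(up = c(take_up, fill_up), down = c(take_dn, fill_dn))
  }

  sigs <- vector("list", nrow(classes_df))
  names(sigs) <- classes_df$drug_id
  for (i in seq_len(nrow(classes_df))) {
    d <- classes_df$drug_id[i]
    cl <- classes_df$class[i]
    up <- cores[[cl]]$up
    dn <- cores[[cl]]$down
    prow <- pairs[pairs$drug_id == d, , drop = FALSE]
    if (nrow(prow)) {
      f <- prow$feature_id[1L]
      frac <- prow$fraction[1L]
      f_up <- truth_feature_set(truth, f, "up")
      f_dn <- truth_feature_set(truth, f, "down")
      if (length(f_up)) up <- union(up, sample(f_up, round(frac * length(f_up))))
      if (length(f_dn)) dn <- union(dn, sample(f_dn, round(frac * length(f_dn))))
    }
    n_priv_up <- max(0L, config$drug_set_size - length(up))
    n_priv_dn <- max(0L, config$drug_set_size - length(dn))
    pool <- setdiff(free_pool, c(up, dn))
    priv <- sample(pool, n_priv_up + n_priv_dn)
    up <- c(up, priv[seq_len(n_priv_up)])
    dn <- c(dn, priv[seq.int(n_priv_up + 1L, length.out = n_priv_dn)])
    sigs[[d]] <- drug_signature(d, up = up, down = dn, universe = genes)
  }
  meta <- do.call(rbind, lapply(sigs, function(s) {
    data.frame(drug_id = s$drug_id, cell_line = s$cell_line, dose = s$dose,
               dose_unit = s$dose_unit, time = s$time, time_unit = s$time_unit,
               stringsAsFactors = FALSE)
  }))
  rownames(meta) <- NULL
  list(signatures = sigs, metadata = meta)
}

#' Simulate the confounded metabolite-gene design
#'
#' The calibration experiment behind covariate adjustment: in each replicate
#' a binary dominance state `D` drives both a metabolite-like variable
#' `x = c * D + noise` and a gene-like variable `y = c * D + noise`, with no
#' direct x-y link. Ordinary Spearman correlation of x and y picks up the
#' confounded association; partial Spearman given `D` should be calibrated at
#' the nominal level. Returns per-replicate p-values from both tests.
#'
#' @param n_reps number of replicates (default 2000).
#' @param n samples per replicate (default 100).
#' @param confound coefficient `c` of the dominance state (default 1.5).
#' @param noise_sd noise standard deviation (default 1).
#' @param seed integer seed.
#' @return data.frame with `p_spearman` and `p_partial`, one row per
#'   replicate.
#' @export
simulate_confounded_design <- function(n_reps = 2000L, n = 100L, confound = 1.5,
                                       noise_sd = 1, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  p_sp <- p_pa <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    repeat {
      D <- stats::rbinom(n, 1L, 0.5)
      if (stats::sd(D) > 0) break
    }
    x <- confound * D + stats::rnorm(n, 0, noise_sd)
    y <- confound * D + stats::rnorm(n, 0, noise_sd)
    p_sp[r] <- spearman_rho(x, y)$p_raw
    p_pa[r] <- partial_spearman_rho(x, y, D)$p_raw
  }
  data.frame(p_spearman = p_sp, p_partial = p_pa)
}

#' Write a synthetic cohort to disk in the pipeline's exchange formats
#'
#' Serializes every matrix, the covariate table, the drug catalog (paired GMT
#' plus metadata TSV) and the planted-truth table into a directory, in the
#' formats the readers of this package consume.
#'
#' @param cohort result of [generate_cohort].
#' @param catalog result of [generate_drug_catalog].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, catalog, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_omics_matrix(cohort$expression, file.path(dir, "expression.tsv"))
  write_omics_matrix(cohort$taxa, file.path(dir, "taxa.tsv"))
  write_omics_matrix(cohort$metabolites, file.path(dir, "metabolites.tsv"))
  write_covariate_table(cohort$covariates, file.path(dir, "covariates.tsv"))
  write_signatures_gmt(catalog$signatures, file.path(dir, "drugs.gmt"))
  utils::write.table(catalog$metadata, file.path(dir, "drug_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_results_tsv(cohort$truth$planted_effects, file.path(dir, "truth.tsv"))
  invisible(dir)
}
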