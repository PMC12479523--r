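small_config <- function(seed,
                         mimicry_pairs = data.frame(
                           feature_id = c("Lactobacillus_crispatus", "taurine"),
                           drug_id = c("d1", "d4"), fraction = 0.5),
                         drug_set_size = 60, class_core_size = 40) {
  generator_config(n_samples = 60, n_genes = 400, n_taxa = 10, n_metabolites = 8,
                   n_drugs = 6,
                   planted_taxon_effects = data.frame(
                     feature_id = rep("Lactobacillus_crispatus", 2),
                     n_genes = 20, effect = 1.5, sign = c(1, -1)),
                   planted_metabolite_effects = data.frame(
                     feature_id = rep("taurine", 2), n_genes = 20, effect = 1.5,
                     sign = c(1, -1), confounded = FALSE),
                   drug_classes = data.frame(
                     drug_id = sprintf("d%d", 1:6),
                     class = rep(c("clsA", "clsB"), each = 3)),
                   mimicry_pairs = mimicry_pairs,
                   drug_set_size = drug_set_size, class_core_size = class_core_size,
                   seed = seed)
}

test_that("the same seed reproduces the cohort and catalog bit for bit", {
  a <- generate_cohort(small_config(123))
  b <- generate_cohort(small_config(123))
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$taxa$values, b$taxa$values)
  expect_identical(a$metabolites$values, b$metabolites$values)
  expect_identical(a$truth$planted_effects, b$truth$planted_effects)
  ca <- generate_drug_catalog(small_config(123), a$truth)
  cb <- generate_drug_catalog(small_config(123), b$truth)
  expect_identical(ca, cb)
  c2 <- generate_cohort(small_config(124))
  expect_false(identical(a$expression$values, c2$expression$values))
})

test_that("generated matrices respect their assay invariants", {
  co <- generate_cohort(small_config(31))
  expect_true(all(co$taxa$values >= 0))
  expect_equal(unname(rowSums(co$taxa$values)), rep(1, 60), tolerance = 1e-12)
  expect_true(all(co$metabolites$values >= 0))
  expect_true(all(is.finite(co$expression$values)))
  expect_setequal(co$covariates$lactobacillus_dominance, c(0, 1))
  # the dominance-tied taxon separates by dominance state
  d <- co$covariates$lactobacillus_dominance == 1
  expect_gt(mean(co$taxa$values[d, "Lactobacillus"]),
            mean(co$taxa$values[!d, "Lactobacillus"]))
})

test_that("config validation catches impossible demands", {
  expect_error(generator_config(seed = NULL), "seed")
  expect_error(generator_config(n_genes = 50, seed = 1), "demand")
  expect_error(small_config(1, mimicry_pairs = data.frame(
    feature_id = "taurine", drug_id = "d1", fraction = 1.5)), "\\(0, 1\\]")
  cfg <- small_config(1, mimicry_pairs = data.frame(
    feature_id = "pyruvate", drug_id = "d1", fraction = 0.5))
  co <- generate_cohort(cfg)
  expect_error(generate_drug_catalog(cfg, co$truth), "effect-free")
})

test_that("planted effects are recoverable and carry the planted sign", {
  co <- generate_cohort(small_config(41))
  rec <- correlate_features(co$taxa, co$expression)
  truth <- co$truth$planted_effects
  tx <- truth[truth$feature_kind == "taxon", ]
  got <- merge(tx, rec, by = c("feature_id", "gene_id"))
  expect_equal(nrow(got), nrow(tx))
  expect_gt(mean(sign(got$rho) == got$sign), 0.95)
  expect_gt(mean(got$q_adj <= 0.05), 0.9)
})

test_that("mimicry overlap 1.0 makes drug sets supersets of the planted sets", {
  cfg <- small_config(51, mimicry_pairs = data.frame(
    feature_id = "taurine", drug_id = "d4", fraction = 1.0))
  co <- generate_cohort(cfg)
  cat_ <- generate_drug_catalog(cfg, co$truth)
  tr <- co$truth$planted_effects
  f_up <- tr$gene_id[tr$feature_id == "taurine" & tr$sign > 0]
  f_dn <- tr$gene_id[tr$feature_id == "taurine" & tr$sign < 0]
  expect_true(all(f_up %in% cat_$signatures$d4$up))
  expect_true(all(f_dn %in% cat_$signatures$d4$down))
})

test_that("classmates share cores; zero private noise means identical signatures", {
  cfg <- small_config(61, drug_set_size = 40, class_core_size = 40)
  co <- generate_cohort(cfg)
  cat_ <- generate_drug_catalog(cfg, co$truth)
  # d2 and d3 are unmimicked classmates with no private genes
  expect_setequal(cat_$signatures$d2$up, cat_$signatures$d3$up)
  expect_setequal(cat_$signatures$d2$down, cat_$signatures$d3$down)
  # identical signatures cluster first: profile each drug by its overlap with
  # the planted feature sets (the mimicked drug d1 stands apart from d2/d3)
  tr <- co$truth$planted_effects
  feats <- unique(tr$feature_id)
  m <- matrix(0, 2 * length(feats), 6,
              dimnames = list(NULL, sprintf("d%d", 1:6)))
  for (d in sprintf("d%d", 1:6)) {
    m[, d] <- unlist(lapply(feats, function(f) {
      c(length(intersect(cat_$signatures[[d]]$up,
                         tr$gene_id[tr$feature_id == f & tr$sign > 0])),
        length(intersect(cat_$signatures[[d]]$down,
                         tr$gene_id[tr$feature_id == f & tr$sign < 0])))
    }))
  }
  dg <- cluster_items(m, "columns")
  expect_equal(dg$height[1], 0)
  expect_setequal(dg$merge[1, ], c(-2L, -3L))
})

test_that("catalog metadata passes the default experiment filter", {
  co <- generate_cohort(small_config(71))
  cat_ <- generate_drug_catalog(small_config(71), co$truth)
  kept <- suppressMessages(filter_catalog(cat_$signatures, catalog_filter()))
  expect_length(kept, 6)
  expect_true(all(cat_$metadata$cell_line == "MCF7"))
  expect_true(all(cat_$metadata$dose == 10))
})

test_that("a cohort and catalog round-trip through the on-disk exchange formats", {
  cfg <- small_config(81)
  co <- generate_cohort(cfg)
  cat_ <- generate_drug_catalog(cfg, co$truth)
  dir <- withr::local_tempdir()
  write_cohort(co, cat_, dir)
  expr <- read_omics_matrix(file.path(dir, "expression.tsv"), "expression")
  expect_equal(expr$values, co$expression$values, tolerance = 1e-12)
  covs <- read_covariate_table(file.path(dir, "covariates.tsv"))
  expect_equal(covs$lactobacillus_dominance, co$covariates$lactobacillus_dominance)
  sigs <- read_drug_signatures(file.path(dir, "drugs.gmt"),
                               file.path(dir, "drug_metadata.tsv"))
  expect_setequal(sigs$d1$up, cat_$signatures$d1$up)
  truth <- read_results_tsv(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), nrow(co$truth$planted_effects))
})

test_that("effect size zero leaves planted pairs indistinguishable from noise", {
  cfg <- generator_config(
    n_samples = 30, n_genes = 200, n_taxa = 5, n_metabolites = 4, n_drugs = 2,
    planted_taxon_effects = data.frame(
      feature_id = "Lactobacillus_crispatus", n_genes = 100, effect = 0, sign = 1),
    planted_metabolite_effects = data.frame(
      feature_id = character(0), n_genes = integer(0), effect = numeric(0),
      sign = numeric(0), confounded = logical(0)),
    drug_classes = data.frame(drug_id = c("d1", "d2"), class = "c1"),
    mimicry_pairs = data.frame(feature_id = character(0), drug_id = character(0),
                               fraction = numeric(0)),
    seed = 91)
  co <- generate_cohort(cfg)
  rec <- correlate_features(co$taxa, co$expression)
  planted <- rec[rec$feature_id == "Lactobacillus_crispatus" &
                   rec$gene_id %in% co$truth$planted_effects$gene_id, ]
  # raw p-values of null planted pairs are uniform (rank statistics are
  # discrete at this n, so tied p-values are expected; the KS tie warning is
  # immaterial)
  expect_gt(suppressWarnings(ks.test(planted$p_raw, "punif"))$p.value, 0.01)
})
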