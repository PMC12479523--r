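make_mat <- function(n = 3, p = 2, kind = "expression", seed = 1) {
  set.seed(seed)
  m <- matrix(abs(rnorm(n * p)), n, p,
              dimnames = list(sprintf("S%02d", 1:n), sprintf("F%02d", 1:p)))
  omics_matrix(m, kind)
}

test_that("delimited matrices round-trip through write and read", {
  x <- make_mat(3, 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_omics_matrix(x, path)
  y <- read_omics_matrix(path, "expression")
  expect_equal(y$values, x$values)
  expect_identical(y$assay_kind, "expression")

  # csv dialect too
  pcsv <- withr::local_tempfile(fileext = ".csv")
  write_omics_matrix(x, pcsv)
  expect_equal(read_omics_matrix(pcsv, "expression")$values, x$values)
})

test_that("on-disk orientation is resolved by identifier matching", {
  x <- make_mat(4, 3, seed = 7)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_omics_matrix(x, p1)
  # write the transposed (features x samples) layout by hand
  tdf <- data.frame(feature_id = colnames(x$values), t(x$values), check.names = FALSE)
  write.table(tdf, p2, sep = "\t", quote = FALSE, row.names = FALSE)

  a <- read_omics_matrix(p1, "expression", orientation = "auto",
                         sample_ids = rownames(x$values))
  b <- read_omics_matrix(p2, "expression", orientation = "auto",
                         sample_ids = rownames(x$values))
  expect_equal(a$values, b$values)
  expect_equal(b$values, x$values)
  expect_error(read_omics_matrix(p2, "expression", orientation = "auto"),
               "sample_ids")
})

test_that("validation rejects duplicates, non-numeric cells and empty input", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("A", "A"), c("g1", "g2")))
  expect_error(omics_matrix(m * 1.0), "duplicate sample.*A")
  m2 <- matrix(1:4, 2, 2, dimnames = list(c("A", "B"), c("g1", "g1")))
  expect_error(omics_matrix(m2 * 1.0), "duplicate feature.*g1")

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tg1\tg2", "A\t1.0\tx", "B\t2\t3"), path)
  expect_error(read_omics_matrix(path, "expression"), "non-numeric.*g2")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tg1\tg2", "A\t1\t2", "A\t3\t4"), path2)
  expect_error(read_omics_matrix(path2, "expression"), "duplicate sample.*A")

  m3 <- matrix(c(-0.1, 1, 2, 3), 2, 2, dimnames = list(c("A", "B"), c("t1", "t2")))
  expect_error(omics_matrix(m3, "taxa"), ">= 0")
  m4 <- matrix(c(Inf, 1, 2, 3), 2, 2, dimnames = list(c("A", "B"), c("g1", "g2")))
  expect_error(omics_matrix(m4), "non-finite")
})

test_that("align_samples intersects, reports drops, and errors on no overlap", {
  mk <- function(ids) {
    omics_matrix(matrix(seq_along(ids) * 1.0, length(ids), 1,
                        dimnames = list(ids, "f")), "expression")
  }
  a <- mk(c("A", "B", "C")); b <- mk(c("B", "C", "D"))
  al <- align_samples(a, b)
  expect_identical(al$samples, c("B", "C"))
  expect_identical(al$dropped[[1]], "A")
  expect_identical(al$dropped[[2]], "D")

  # identical sample sets pass through order-normalized
  c2 <- mk(c("C", "A", "B"))
  al2 <- align_samples(a, c2)
  expect_identical(al2$samples, c("A", "B", "C"))
  expect_identical(rownames(al2$matrices[[2]]$values), c("A", "B", "C"))

  expect_error(align_samples(mk(c("A", "B")), mk(c("X", "Y"))),
               "no samples shared.*2, 2")
})

test_that("align_samples is idempotent and order-independent, with covariates", {
  set.seed(3)
  ids <- sprintf("P%02d", 1:8)
  a <- omics_matrix(matrix(rnorm(16), 8, 2, dimnames = list(ids, c("f1", "f2"))),
                    "expression")
  b <- omics_matrix(matrix(abs(rnorm(12)), 6, 2,
                           dimnames = list(sample(ids)[1:6], c("t1", "t2"))), "taxa")
  cov <- covariate_table(rev(ids), lactobacillus_dominance = rep(c(0, 1), 4))

  al1 <- align_samples(a, b, covariates = cov)
  al2 <- align_samples(al1$matrices[[1]], al1$matrices[[2]], covariates = al1$covariates)
  expect_equal(al2$matrices[[1]]$values, al1$matrices[[1]]$values)
  expect_equal(al2$covariates, al1$covariates, ignore_attr = TRUE)
  expect_true(all(lengths(al2$dropped) == 0))

  # permuting an input's sample order yields identical aligned content
  perm <- b$values[sample(nrow(b$values)), , drop = FALSE]
  al3 <- align_samples(a, omics_matrix(perm, "taxa"), covariates = cov)
  expect_equal(al3$matrices[[2]]$values, al1$matrices[[2]]$values)

  # covariate table follows the canonical sample order
  expect_identical(al1$covariates$sample_id, al1$samples)
})

test_that("a cohort-sized alignment keeps only matched participants", {
  # 90 biopsy samples vs 23 with matched metabolomics
  ids <- sprintf("P%02d", 1:90)
  a <- omics_matrix(matrix(rnorm(90), 90, 1, dimnames = list(ids, "g")), "expression")
  sub <- sort(sample(ids, 23))
  b <- omics_matrix(matrix(abs(rnorm(23)), 23, 1, dimnames = list(sub, "m")), "metabolite")
  al <- align_samples(a, b)
  expect_length(al$samples, 23)
  expect_length(al$dropped[[1]], 67)
})

test_that("covariate tables validate and round-trip", {
  expect_error(covariate_table(c("A", "A"), x = c(1, 2)), "duplicate")
  expect_error(covariate_table(c("A", "B"), c(1, 2)), "named")
  cov <- covariate_table(c("A", "B"), lactobacillus_dominance = c(1, 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_covariate_table(cov, path)
  expect_equal(read_covariate_table(path), cov, ignore_attr = TRUE)
})
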