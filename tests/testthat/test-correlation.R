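test_that("perfect monotone and antitone relationships give rho of +/-1, p of 0", {
  r1 <- spearman_rho(c(1, 2, 3, 4), c(10, 20, 30, 40))
  expect_equal(r1$rho, 1)
  expect_equal(r1$p_raw, 0)
  r2 <- spearman_rho(c(1, 2, 3, 4), c(8, 6, 4, 2))
  expect_equal(r2$rho, -1)
  # nonlinear but monotone is still perfect
  expect_equal(spearman_rho(1:6, exp(1:6))$rho, 1)
})

test_that("spearman is exactly invariant under strictly increasing transforms", {
  set.seed(21)
  for (i in 1:20) {
    x <- round(rnorm(15), 1)   # ties likely
    y <- round(rnorm(15), 1)
    base <- spearman_rho(x, y)
    tr <- spearman_rho(exp(x), y^3 + 2 * y)
    expect_identical(tr$rho, base$rho)
    expect_identical(tr$p_raw, base$p_raw)
  }
})

test_that("spearman handles missing values pairwise and rejects degenerate input", {
  x <- c(1, 2, NA, 4, 5); y <- c(2, NA, 3, 8, 10)
  r <- spearman_rho(x, y)
  expect_equal(r$n_used, 3)
  expect_error(spearman_rho(c(1, 1, 1, 1), c(1, 2, 3, 4)), "constant")
  expect_error(spearman_rho(c(1, 2), c(3, 4)), "fewer than 3")
})

test_that("exact permutation p-values agree with the t approximation in direction", {
  set.seed(5)
  x <- rnorm(7); y <- x + rnorm(7, 0, 0.3)
  ex <- spearman_rho(x, y, exact = TRUE)
  ap <- spearman_rho(x, y)
  expect_identical(ex$rho, ap$rho)
  expect_gt(ex$p_raw, 0)
  expect_lt(ex$p_raw, 0.1)
  expect_error(spearman_rho(rnorm(10), rnorm(10), exact = TRUE), "n <= 9")
})

test_that("partial spearman with empty covariates is bitwise plain spearman", {
  set.seed(31)
  x <- round(rnorm(30), 1); y <- round(rnorm(30), 1)
  expect_identical(partial_spearman_rho(x, y, NULL), spearman_rho(x, y))
  expect_identical(partial_spearman_rho(x, y, data.frame()), spearman_rho(x, y))
})

test_that("partial spearman detects collinear and fully-explained inputs", {
  set.seed(41)
  x <- rnorm(20); y <- rnorm(20); z <- rnorm(20)
  expect_error(partial_spearman_rho(x, y, cbind(z, 2 * z)), "rank-deficient")
  # x identical to the covariate: residual ranks are all zero
  expect_error(partial_spearman_rho(z, y, z), "fully explained")
})

test_that("bh_adjust matches the hand step-up on the worked example", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), c(0.04, 0.04, 0.04, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("bh_adjust is permutation-equivariant and monotone in sorted order", {
  set.seed(51)
  p <- runif(40)
  q <- bh_adjust(p)
  perm <- sample(40)
  expect_identical(bh_adjust(p[perm]), q[perm])
  expect_true(all(diff(q[order(p)]) >= 0))
})

test_that("correlate_features yields one record per pair on complete data", {
  set.seed(61)
  ids <- sprintf("S%02d", 1:20)
  f <- omics_matrix(matrix(abs(rnorm(40)), 20, 2,
                           dimnames = list(ids, c("tA", "tB"))), "taxa")
  e <- omics_matrix(matrix(rnorm(60), 20, 3,
                           dimnames = list(ids, c("g1", "g2", "g3"))), "expression")
  rec <- correlate_features(f, e)
  expect_equal(nrow(rec), 6)
  expect_setequal(rec$method, "spearman")
  expect_true(all(rec$n_used == 20))

  # each record agrees with the scalar routine
  for (i in seq_len(nrow(rec))) {
    r <- spearman_rho(f$values[, rec$feature_id[i]], e$values[, rec$gene_id[i]])
    expect_equal(rec$rho[i], r$rho, tolerance = 1e-12)
    expect_equal(rec$p_raw[i], r$p_raw, tolerance = 1e-12)
  }
})

test_that("the fast matrix path and the pairwise path agree in the presence of NAs", {
  set.seed(71)
  ids <- sprintf("S%02d", 1:25)
  fv <- matrix(abs(rnorm(50)), 25, 2, dimnames = list(ids, c("tA", "tB")))
  ev <- matrix(rnorm(75), 25, 3, dimnames = list(ids, c("g1", "g2", "g3")))
  complete <- correlate_features(omics_matrix(fv, "taxa"), omics_matrix(ev, "expression"))
  ev_na <- ev; ev_na[1, 1] <- NA   # forces the pairwise path
  partial <- correlate_features(omics_matrix(fv, "taxa"), omics_matrix(ev_na, "expression"))
  shared <- partial$gene_id != "g1"
  expect_equal(partial$rho[shared], complete$rho[complete$gene_id != "g1"],
               tolerance = 1e-12)
  expect_true(all(partial$n_used[partial$gene_id == "g1"] == 24))
})

test_that("constant features produce no records and one warning", {
  ids <- sprintf("S%02d", 1:12)
  fv <- matrix(c(rep(0.5, 12), abs(rnorm(12))), 12, 2,
               dimnames = list(ids, c("const", "ok")))
  ev <- matrix(rnorm(24), 12, 2, dimnames = list(ids, c("g1", "g2")))
  expect_warning(
    rec <- correlate_features(omics_matrix(fv, "taxa"), omics_matrix(ev, "expression")),
    "skipped")
  expect_false("const" %in% rec$feature_id)
  expect_equal(nrow(rec), 2)
})

test_that("partial correlation in correlate_features controls the named covariate", {
  set.seed(81)
  n <- 60
  ids <- sprintf("S%02d", 1:n)
  D <- rbinom(n, 1, 0.5)
  met <- exp(1.5 * D + rnorm(n))
  gene <- 1.5 * D + rnorm(n)
  f <- omics_matrix(matrix(met, n, 1, dimnames = list(ids, "m1")), "metabolite")
  e <- omics_matrix(matrix(gene, n, 1, dimnames = list(ids, "g1")), "expression")
  cov <- covariate_table(ids, lactobacillus_dominance = D)

  plain <- correlate_features(f, e)
  adj <- correlate_features(f, e, covariates = cov,
                            config = correlation_config(
                              covariate_names = "lactobacillus_dominance"))
  expect_identical(adj$method, "partial_spearman")
  expect_lt(plain$p_raw, 0.05)        # confounded association looks real
  expect_gt(adj$p_raw, plain$p_raw)   # adjustment removes it
  # matches the scalar partial routine
  ref <- partial_spearman_rho(met, gene, D)
  expect_equal(adj$rho, ref$rho, tolerance = 1e-12)
  expect_equal(adj$p_raw, ref$p_raw, tolerance = 1e-12)
})

test_that("BH families are per feature by default, global on request", {
  set.seed(91)
  ids <- sprintf("S%02d", 1:15)
  f <- omics_matrix(matrix(abs(rnorm(30)), 15, 2, dimnames = list(ids, c("tA", "tB"))),
                    "taxa")
  e <- omics_matrix(matrix(rnorm(75), 15, 5, dimnames = list(ids, sprintf("g%d", 1:5))),
                    "expression")
  per <- correlate_features(f, e)
  glob <- correlate_features(f, e, config = correlation_config(adjust_scope = "global"))
  for (feat in c("tA", "tB")) {
    sub <- per[per$feature_id == feat, ]
    expect_equal(sub$q_adj, bh_adjust(sub$p_raw))
  }
  expect_equal(glob$q_adj, bh_adjust(glob$p_raw))
})

test_that("extract_signature partitions by sign at the threshold", {
  rec <- data.frame(
    feature_id = "tA",
    gene_id = sprintf("g%d", 1:5),
    rho = c(0.6, -0.5, 0.4, 0, -0.9),
    n_used = 10, p_raw = 0.001,
    q_adj = c(0.01, 0.02, 0.2, 0.01, 0.04),
    method = "spearman", stringsAsFactors = FALSE)
  u <- sprintf("g%d", 1:5)
  sig <- extract_signature(rec, u, alpha = 0.05)
  expect_identical(sig$up, "g1")              # g3 fails alpha, g4 has rho 0
  expect_setequal(sig$down, c("g2", "g5"))

  # alpha = 1 partitions every non-zero-rho gene
  sig1 <- extract_signature(rec, u, alpha = 1)
  expect_setequal(union(sig1$up, sig1$down), c("g1", "g2", "g3", "g5"))
  expect_length(intersect(sig1$up, sig1$down), 0)

  # all above alpha: both sets empty
  rec$q_adj <- 0.5
  sig0 <- extract_signature(rec, u, alpha = 0.05)
  expect_length(sig0$up, 0); expect_length(sig0$down, 0)

  # brute-force filter agreement on random records
  set.seed(101)
  recr <- data.frame(feature_id = "f", gene_id = sprintf("g%d", 1:50),
                     rho = runif(50, -1, 1), n_used = 10, p_raw = 0.1,
                     q_adj = runif(50), method = "spearman")
  s <- extract_signature(recr, recr$gene_id, alpha = 0.3)
  expect_setequal(s$up, recr$gene_id[recr$q_adj <= 0.3 & recr$rho > 0])
  expect_setequal(s$down, recr$gene_id[recr$q_adj <= 0.3 & recr$rho < 0])

  expect_error(extract_signature(rbind(rec, transform(rec, feature_id = "tB")), u),
               "single feature")
})
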