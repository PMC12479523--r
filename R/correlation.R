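#' Midranks
#'
#' Average ranks with ties shared (midranks), `NA` kept in place. Midranks are
#' used everywhere ranks are needed so that results are deterministic and agree
#' with the default tie handling of `stats::cor.test(method = "spearman")`.
#'
#' @param x numeric vector.
#' @return numeric vector of ranks.
#' @export
midrank <- function(x) rank(x, ties.method = "average", na.last = "keep")

cor_p_from_t <- function(rho, df) {
  if (is.na(rho)) return(NA_real_)
  if (abs(rho) >= 1 - 1e-12) return(0)
  tstat <- rho * sqrt(df / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    q <- p + (p >= i)
    out[[i]] <- cbind(rep.int(i, nrow(q)), q, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Spearman rank correlation with a two-sided p-value
#'
#' Computes rho as the Pearson correlation of midranks over pairwise-complete
#' observations. The p-value uses the asymptotic t approximation,
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (two-sided), the default behavior of `cor.test` in the presence of ties;
#' `exact = TRUE` instead enumerates all permutations (only for n <= 9).
#' Monotone relationships are the target: any strictly increasing transform of
#' either variable leaves the result unchanged.
#'
#' @param x,y numeric vectors of equal length.
#' @param exact use exact permutation enumeration for the p-value (n <= 9).
#' @return a list with `rho`, `p_raw`, `n_used`, and `method = "spearman"`.
#' @export
spearman_rho <- function(x, y, exact = FALSE) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("fewer than 3 complete pairs", call. = FALSE)
  rx <- midrank(x); ry <- midrank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("undefined correlation: constant vector after pairwise filtering", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  rho <- max(-1, min(1, rho))
  if (exact) {
    if (n > 9L) stop("exact permutation p-value supported only for n <= 9", call. = FALSE)
    P <- all_permutations(n)
    ryc <- ry - mean(ry)
    rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    sums <- matrix(ryc[P], nrow(P), n) %*% rxc
    rho_perm <- as.numeric(sums) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    p <- cor_p_from_t(rho, n - 2)
  }
  list(rho = rho, p_raw = p, n_used = n, method = "spearman")
}

#' Partial Spearman correlation given covariates
#'
#' Midrank-transforms `x`, `y` and each covariate column, removes the linear
#' contribution of the ranked covariates from ranked `x` and ranked `y` by
#' least squares, and correlates the residuals (the standard
#' rank-then-residualize definition of partial Spearman). The p-value is the
#' two-sided t test on `n - 2 - k` degrees of freedom, `k` the number of
#' covariates. Rows with a missing value in `x`, `y`, or any covariate are
#' dropped listwise. With no covariates this is exactly [spearman_rho].
#'
#' @param x,y numeric vectors.
#' @param z covariate vector, matrix or data.frame (columns = covariates), or
#'   `NULL` for none.
#' @return a list with `rho`, `p_raw`, `n_used`, and `method`.
#' @export
partial_spearman_rho <- function(x, y, z = NULL) {
  if (is.null(z) || NCOL(z) == 0L || length(z) == 0L) {
    return(spearman_rho(x, y))
  }
  z <- as.matrix(as.data.frame(z))
  storage.mode(z) <- "double"
  stopifnot(length(x) == length(y), nrow(z) == length(x))
  k <- ncol(z)
  ok <- stats::complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok, , drop = FALSE]
  n <- length(x)
  if (n < k + 3L) stop("fewer than k + 3 complete rows for partial correlation", call. = FALSE)
  rx <- midrank(x); ry <- midrank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("undefined correlation: constant vector after listwise filtering", call. = FALSE)
  }
  rz <- apply(z, 2L, midrank)
  X <- cbind(1, rz)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("covariate matrix is rank-deficient (collinear covariates)", call. = FALSE)
  }
  res_x <- qr.resid(qx, rx)
  res_y <- qr.resid(qx, ry)
  if (stats::sd(res_x) < 1e-12 || stats::sd(res_y) < 1e-12) {
    stop("undefined correlation: variable fully explained by covariates", call. = FALSE)
  }
  rho <- stats::cor(res_x, res_y)
  rho <- max(-1, min(1, rho))
  p <- cor_p_from_t(rho, n - 2 - k)
  list(rho = rho, p_raw = p, n_used = n, method = "partial_spearman")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`q_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1,
#' mapped back to input order), delegated to `stats::p.adjust(method = "BH")`,
#' the routine whose adjusted values the screen reports as Q-values. Input
#' order of ties is preserved.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must all lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Configuration for signature extraction
#'
#' @param alpha adjusted-p significance threshold for up/down gene lists
#'   (default 0.05).
#' @param adjust_scope BH family definition: `"per_feature"` adjusts each
#'   feature's gene family separately (matching per-feature gene-list
#'   construction); `"global"` adjusts one family over all pairs.
#' @param min_pairs minimum complete pairs for a record to be reported
#'   (default 5, never below 3).
#' @param covariate_names covariate columns used for partial correlation;
#'   empty means ordinary Spearman.
#' @param exact use exact permutation p-values for tiny n (<= 9), ordinary
#'   Spearman only.
#' @return a list of class `correlation_config`.
#' @export
correlation_config <- function(alpha = 0.05,
                               adjust_scope = c("per_feature", "global"),
                               min_pairs = 5L,
                               covariate_names = character(0),
                               exact = FALSE) {
  adjust_scope <- match.arg(adjust_scope)
  stopifnot(alpha > 0, alpha < 1, min_pairs >= 3L)
  structure(list(alpha = alpha, adjust_scope = adjust_scope,
                 min_pairs = as.integer(min_pairs),
                 covariate_names = covariate_names, exact = exact),
            class = "correlation_config")
}

# rank every column; returns list(ranks = matrix, constant = logical per column)
rank_columns <- function(m) {
  r <- apply(m, 2L, midrank)
  if (!is.matrix(r)) r <- matrix(r, ncol = ncol(m), dimnames = dimnames(m))
  const <- apply(r, 2L, function(v) {
    v <- v[!is.na(v)]
    length(v) == 0L || max(v) == min(v)
  })
  list(ranks = r, constant = const)
}

#' Correlate every feature against every gene
#'
#' Computes one association record per (feature, gene): Spearman rho when no
#' covariates are configured, partial Spearman given the named covariate
#' columns otherwise (the design used to control metabolite-gene associations
#' for Lactobacillus dominance). Raw p-values are BH-adjusted within the
#' configured family scope. When the aligned matrices are complete (no missing
#' cells) a vectorized rank-and-correlate path is used; with missing cells each
#' pair is computed on its pairwise- (or listwise-) complete rows and records
#' with fewer than `min_pairs` observations are dropped. Constant features or
#' genes yield no records and are counted in one warning.
#'
#' @param features [omics_matrix] of taxa or metabolites (samples x features).
#' @param expression [omics_matrix] of host expression (samples x genes).
#' @param covariates optional [covariate_table]; required when
#'   `config$covariate_names` is non-empty.
#' @param config a [correlation_config].
#' @return data.frame with columns `feature_id`, `gene_id`, `rho`, `n_used`,
#'   `p_raw`, `q_adj`, `method`.
#' @export
correlate_features <- function(features, expression, covariates = NULL,
                               config = correlation_config()) {
  stopifnot(inherits(features, "omics_matrix"), inherits(expression, "omics_matrix"))
  fs <- rownames(features$values); es <- rownames(expression$values)
  if (!identical(fs, es)) {
    stop("inputs are not sample-aligned; run align_samples() first", call. = FALSE)
  }
  method <- "spearman"
  Z <- NULL
  if (length(config$covariate_names)) {
    if (is.null(covariates)) {
      stop("covariate_names configured but no covariates supplied", call. = FALSE)
    }
    missing_cov <- setdiff(config$covariate_names, names(covariates))
    if (length(missing_cov)) {
      stop("covariates lack columns: ", paste(missing_cov, collapse = ", "), call. = FALSE)
    }
    if (!all(fs %in% covariates$sample_id)) {
      stop("covariate table does not cover all aligned samples", call. = FALSE)
    }
    Z <- as.matrix(covariates[match(fs, covariates$sample_id),
                              config$covariate_names, drop = FALSE])
    storage.mode(Z) <- "double"
    if (anyNA(Z)) stop("missing values in covariates used for adjustment", call. = FALSE)
    method <- "partial_spearman"
  }

  F_ids <- colnames(features$values)
  G_ids <- colnames(expression$values)
  complete <- !anyNA(features$values) && !anyNA(expression$values)

  if (complete) {
    out <- correlate_fast(features$values, expression$values, Z, method)
  } else {
    out <- correlate_pairwise(features$values, expression$values, Z, method, config)
  }
  n_skipped <- attr(out, "n_skipped")
  if (n_skipped > 0L) {
    warning(sprintf("%d (feature, gene) pair(s) skipped (constant or too few complete pairs)",
                    n_skipped))
  }
  out <- out[out$n_used >= config$min_pairs, , drop = FALSE]

  if (nrow(out)) {
    if (config$adjust_scope == "per_feature") {
      q <- numeric(nrow(out))
      for (f in unique(out$feature_id)) {
        idx <- which(out$feature_id == f)
        q[idx] <- bh_adjust(out$p_raw[idx])
      }
      out$q_adj <- q
    } else {
      out$q_adj <- bh_adjust(out$p_raw)
    }
  } else {
    out$q_adj <- numeric(0)
  }
  out <- out[, c("feature_id", "gene_id", "rho", "n_used", "p_raw", "q_adj", "method")]
  rownames(out) <- NULL
  out
}

correlate_fast <- function(fm, em, Z, method) {
  n <- nrow(fm)
  rf <- rank_columns(fm); re <- rank_columns(em)
  keep_f <- !rf$constant; keep_g <- !re$constant
  n_skipped <- sum(!keep_f) * ncol(em) + sum(keep_f) * sum(!keep_g)
  RF <- rf$ranks[, keep_f, drop = FALSE]
  RE <- re$ranks[, keep_g, drop = FALSE]
  k <- 0L
  if (!is.null(Z)) {
    k <- ncol(Z)
    X <- cbind(1, apply(Z, 2L, midrank))
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      stop("covariate matrix is rank-deficient (collinear covariates)", call. = FALSE)
    }
    RF <- qr.resid(qx, RF)
    RE <- qr.resid(qx, RE)
    # residuals can degenerate when a variable is fully covariate-explained
    sd_f <- apply(RF, 2L, stats::sd); sd_g <- apply(RE, 2L, stats::sd)
    drop_f <- sd_f < 1e-12; drop_g <- sd_g < 1e-12
    n_skipped <- n_skipped + sum(drop_f) * ncol(RE) +
      sum(!drop_f) * sum(drop_g)
    RF <- RF[, !drop_f, drop = FALSE]
    RE <- RE[, !drop_g, drop = FALSE]
  }
  if (ncol(RF) == 0L || ncol(RE) == 0L) {
    out <- data.frame(feature_id = character(0), gene_id = character(0),
                      rho = numeric(0), n_used = integer(0), p_raw = numeric(0),
                      method = character(0), stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  rho <- stats::cor(RF, RE)             # features x genes
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  df <- n - 2 - k
  tt <- rho * sqrt(df / pmax(1 - rho^2, 1e-300))
  p <- 2 * stats::pt(-abs(tt), df)
  p[abs(rho) >= 1 - 1e-12] <- 0
  out <- data.frame(
    feature_id = rep(rownames(rho), times = ncol(rho)),
    gene_id = rep(colnames(rho), each = nrow(rho)),
    rho = as.numeric(rho),
    n_used = n,
    p_raw = as.numeric(p),
    method = method,
    stringsAsFactors = FALSE
  )
  # feature-major ordering
  out <- out[order(match(out$feature_id, rownames(rho))), , drop = FALSE]
  attr(out, "n_skipped") <- n_skipped
  out
}

correlate_pairwise <- function(fm, em, Z, method, config) {
  rows <- vector("list", ncol(fm) * ncol(em))
  n_skipped <- 0L
  idx <- 0L
  for (i in seq_len(ncol(fm))) {
    for (j in seq_len(ncol(em))) {
      idx <- idx + 1L
      r <- tryCatch(
        if (is.null(Z)) spearman_rho(fm[, i], em[, j], exact = config$exact)
        else partial_spearman_rho(fm[, i], em[, j], Z),
        error = function(e) NULL
      )
      if (is.null(r) || r$n_used < config$min_pairs) {
        n_skipped <- n_skipped + 1L
        next
      }
      rows[[idx]] <- data.frame(feature_id = colnames(fm)[i], gene_id = colnames(em)[j],
                                rho = r$rho, n_used = r$n_used, p_raw = r$p_raw,
                                method = method, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(feature_id = character(0), gene_id = character(0),
                      rho = numeric(0), n_used = integer(0), p_raw = numeric(0),
                      method = character(0), stringsAsFactors = FALSE)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Cut a feature's correlation records into an up/down gene signature
#'
#' Genes with `q_adj <= alpha` enter the up set when rho > 0 and the down set
#' when rho < 0 (positive correlation read as upregulation, negative as
#' downregulation); rho exactly 0 has no direction and enters neither set.
#'
#' @param records data.frame of correlation records for a single feature.
#' @param universe gene universe the records were tested over.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return a [gene_signature].
#' @export
extract_signature <- function(records, universe, alpha = 0.05) {
  stopifnot(all(c("feature_id", "gene_id", "rho", "q_adj") %in% names(records)))
  fid <- unique(records$feature_id)
  if (length(fid) != 1L) {
    stop("records must belong to a single feature; got: ",
         paste(utils::head(fid, 5L), collapse = ", "), call. = FALSE)
  }
  sig <- records$q_adj <= alpha
  gene_signature(fid,
                 up = records$gene_id[sig & records$rho > 0],
                 down = records$gene_id[sig & records$rho < 0],
                 universe = universe, alpha = alpha)
}

#' Extract signatures for every feature in a correlation table
#'
#' @param records data.frame from [correlate_features].
#' @param universe gene universe.
#' @param alpha adjusted-p threshold.
#' @return named list of [gene_signature] objects, one per feature present.
#' @export
extract_signatures <- function(records, universe, alpha = 0.05) {
  feats <- unique(records$feature_id)
  out <- lapply(feats, function(f) {
    extract_signature(records[records$feature_id == f, , drop = FALSE], universe, alpha)
  })
  names(out) <- feats
  out
}

#' Read / write tidy result tables
#'
#' Correlation records and overlap results are serialized as plain tidy TSV,
#' one row per record.
#'
#' @param df a data.frame.
#' @param path file path.
#' @return `path` (write) or a data.frame (read).
#' @export
write_results_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_tsv
#' @export
read_results_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
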