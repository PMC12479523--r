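#' Screen configuration
#'
#' @param universe_policy how the Fisher universe is formed:
#'   `"intersection"` (default) of the feature-signature universe and the
#'   drug-catalog universe — overlap is only observable among genes measurable
#'   on both platforms; `"union"`; or `"explicit"` with `universe` supplied.
#'   This is the single most result-sensitive choice in the screen and is
#'   recorded on every result table as an attribute.
#' @param alternative `"two_sided"` (default, the minimum-likelihood exact
#'   rule) or `"greater"` (enrichment only).
#' @param bh_scope BH family: `"per_direction"` (default; all feature x drug
#'   pairs within one direction, the family a per-direction heatmap compares
#'   across), `"global"`, `"per_drug"`, or `"per_feature"`.
#' @param neglog_cap cap for -log10(Q); Q = 0 maps to the cap (default 16).
#' @param universe explicit gene universe for `universe_policy = "explicit"`.
#' @param include_reversal also run cross-direction (feature-up vs drug-down
#'   and vice versa) anti-mimicry comparisons; off by default.
#' @return a list of class `screen_config`.
#' @export
screen_config <- function(universe_policy = c("intersection", "union", "explicit"),
                          alternative = c("two_sided", "greater"),
                          bh_scope = c("per_direction", "global", "per_drug", "per_feature"),
                          neglog_cap = 16, universe = NULL,
                          include_reversal = FALSE) {
  universe_policy <- match.arg(universe_policy)
  alternative <- match.arg(alternative)
  bh_scope <- match.arg(bh_scope)
  stopifnot(neglog_cap > 0)
  if (universe_policy == "explicit" && is.null(universe)) {
    stop("universe_policy = \"explicit\" requires `universe`", call. = FALSE)
  }
  structure(list(universe_policy = universe_policy, alternative = alternative,
                 bh_scope = bh_scope, neglog_cap = neglog_cap,
                 universe = universe, include_reversal = include_reversal),
            class = "screen_config")
}

#' Fisher's exact overlap of two gene sets
#'
#' Forms the 2x2 contingency table of two gene sets over a shared universe
#' (`k = |A and B|`, `|A only|`, `|B only|`, `|neither|`) and computes the
#' exact hypergeometric p-value: for `alternative = "greater"`,
#' `P(X >= k)`; for `"two_sided"`, the sum of probabilities of all tables with
#' the same margins whose point probability does not exceed that of the
#' observed table (up to a relative tolerance of 1e-7), i.e. the convention of
#' `stats::fisher.test`. Genes outside the universe are trimmed with a warning
#' before testing. The test is symmetric in its two sets. The odds ratio is
#' the sample ratio `(k * |neither|) / (|A only| * |B only|)`, with `x/0`
#' giving `Inf` and `0/0` giving `NaN`.
#'
#' @param set_a,set_b character vectors of gene identifiers.
#' @param universe character vector, the background (length >= 2).
#' @param alternative `"two_sided"` or `"greater"`.
#' @return list with `k_overlap`, `n_feature_only` (A only), `n_drug_only`
#'   (B only), `n_neither`, `odds_ratio`, `p_raw`.
#' @export
fisher_overlap <- function(set_a, set_b, universe,
                           alternative = c("two_sided", "greater")) {
  alternative <- match.arg(alternative)
  universe <- unique(as.character(universe))
  if (length(universe) < 2L) stop("universe must contain at least 2 genes", call. = FALSE)
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  out_a <- setdiff(set_a, universe); out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b)) {
    warning(sprintf("trimmed %d gene(s) outside the universe before testing",
                    length(out_a) + length(out_b)))
    set_a <- intersect(set_a, universe)
    set_b <- intersect(set_b, universe)
  }
  k <- length(intersect(set_a, set_b))
  a_only <- length(set_a) - k
  b_only <- length(set_b) - k
  neither <- length(universe) - k - a_only - b_only
  p <- overlap_p(k, length(set_a), length(set_b), length(universe), alternative)
  num <- as.numeric(k) * neither
  den <- as.numeric(a_only) * b_only
  or <- if (den == 0 && num == 0) NaN else if (den == 0) Inf else num / den
  list(k_overlap = k, n_feature_only = a_only, n_drug_only = b_only,
       n_neither = neither, odds_ratio = or, p_raw = p)
}

# exact p for overlap k between sets of sizes na, nb in universe nu
overlap_p <- function(k, na, nb, nu, alternative) {
  if (alternative == "greater") {
    return(stats::phyper(k - 1, na, nu - na, nb, lower.tail = FALSE))
  }
  if (na == 0L || nb == 0L || na == nu || nb == nu) return(1)
  p <- stats::fisher.test(matrix(c(k, na - k, nb - k, nu - na - nb + k), nrow = 2L),
                          alternative = "two.sided")$p.value
  min(p, 1)
}

#' Run the directional mimicry screen
#'
#' The core comparison: for every (feature, drug) pair, the feature's up set
#' is tested against the drug's up set and the feature's down set against the
#' drug's down set (genes positively associated with the feature vs
#' drug-induced genes; negatively associated vs drug-suppressed genes),
#' each with [fisher_overlap] over the configured universe. P-values are
#' BH-adjusted within `config$bh_scope` and reported with a capped
#' `-log10(Q)`. Features whose up and down sets are both empty (after
#' universe trimming) are skipped with a warning. Output is deterministic and
#' invariant to the input order of features and drugs, up to row order.
#'
#' @param feature_sigs list of [gene_signature] objects.
#' @param drug_sigs list of [drug_signature] objects.
#' @param config a [screen_config].
#' @return data.frame with one row per (feature, drug, direction):
#'   `feature_id`, `drug_id`, `direction`, contingency counts, `odds_ratio`,
#'   `p_raw`, `q_adj`, `neg_log10_q`. The universe used is attached as
#'   `attr(, "universe")`.
#' @export
run_screen <- function(feature_sigs, drug_sigs, config = screen_config()) {
  stopifnot(length(feature_sigs) > 0L, length(drug_sigs) > 0L)
  feat_universe <- unique(unlist(lapply(feature_sigs, `[[`, "universe"), use.names = FALSE))
  drug_universe <- unique(unlist(lapply(drug_sigs, `[[`, "universe"), use.names = FALSE))
  universe <- switch(config$universe_policy,
    intersection = intersect(feat_universe, drug_universe),
    union = union(feat_universe, drug_universe),
    explicit = unique(as.character(config$universe))
  )
  if (length(universe) < 2L) {
    stop("screen universe has fewer than 2 genes under policy '",
         config$universe_policy, "'", call. = FALSE)
  }
  nu <- length(universe)

  directions <- list(c("up", "up"), c("down", "down"))
  if (config$include_reversal) {
    directions <- c(directions, list(c("up", "down"), c("down", "up")))
  }

  skipped <- character(0)
  rows <- list()
  for (fi in seq_along(feature_sigs)) {
    fs <- feature_sigs[[fi]]
    f_up <- intersect(fs$up, universe)
    f_dn <- intersect(fs$down, universe)
    if (length(f_up) == 0L && length(f_dn) == 0L) {
      skipped <- c(skipped, fs$feature_id)
      next
    }
    for (di in seq_along(drug_sigs)) {
      ds <- drug_sigs[[di]]
      d_up <- intersect(ds$up, universe)
      d_dn <- intersect(ds$down, universe)
      for (dir in directions) {
        a <- if (dir[1L] == "up") f_up else f_dn
        b <- if (dir[2L] == "up") d_up else d_dn
        k <- length(intersect(a, b))
        p <- overlap_p(k, length(a), length(b), nu, config$alternative)
        num <- as.numeric(k) * (nu - length(a) - length(b) + k)
        den <- as.numeric(length(a) - k) * (length(b) - k)
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = fs$feature_id, drug_id = ds$drug_id,
          direction = if (dir[1L] == dir[2L]) dir[1L] else paste(dir, collapse = "_vs_"),
          k_overlap = k, n_feature_only = length(a) - k,
          n_drug_only = length(b) - k,
          n_neither = nu - length(a) - length(b) + k,
          odds_ratio = if (den == 0 && num == 0) NaN else if (den == 0) Inf else num / den,
          p_raw = p, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(skipped)) {
    message(sprintf("run_screen: skipped %d feature(s) with empty up and down sets",
                    length(skipped)))
  }
  if (length(rows) == 0L) {
    out <- data.frame(feature_id = character(0), drug_id = character(0),
                      direction = character(0), k_overlap = integer(0),
                      n_feature_only = integer(0), n_drug_only = integer(0),
                      n_neither = integer(0), odds_ratio = numeric(0),
                      p_raw = numeric(0), q_adj = numeric(0),
                      neg_log10_q = numeric(0), stringsAsFactors = FALSE)
    attr(out, "universe") <- universe
    return(out)
  }
  out <- do.call(rbind, rows)

  out$q_adj <- NA_real_
  fam <- switch(config$bh_scope,
    per_direction = out$direction,
    global = rep("all", nrow(out)),
    per_drug = paste(out$drug_id, out$direction),
    per_feature = paste(out$feature_id, out$direction)
  )
  for (f in unique(fam)) {
    idx <- which(fam == f)
    out$q_adj[idx] <- bh_adjust(out$p_raw[idx])
  }
  out$neg_log10_q <- neg_log10_capped(out$q_adj, config$neglog_cap)
  rownames(out) <- NULL
  attr(out, "universe") <- universe
  attr(out, "universe_policy") <- config$universe_policy
  out
}

#' Capped -log10 transform
#'
#' `min(cap, -log10(q))`, with `q = 0` mapping to the cap. Keeps heatmap
#' values finite and serializable.
#'
#' @param q numeric vector of adjusted p-values.
#' @param cap positive cap (default 16).
#' @return numeric vector in \[0, cap\].
#' @export
neg_log10_capped <- function(q, cap = 16) {
  stopifnot(cap > 0)
  out <- ifelse(q <= 0, cap, pmin(cap, -log10(q)))
  pmax(out, 0)
}

#' Build a features x drugs similarity matrix of -log10(Q)
#'
#' Pivots one direction of the screen results into the matrix plotted as a
#' concordance heatmap. Row and column order follow order of first appearance
#' in `results`. Pairs missing from the grid are filled with 0 ("no evidence
#' of similarity") and counted in `attr(, "n_filled")`; duplicated
#' (feature, drug) rows within the direction are an integrity error.
#'
#' @param results data.frame from [run_screen].
#' @param direction `"up"` or `"down"`.
#' @return numeric matrix (features x drugs) of capped -log10(Q).
#' @export
build_similarity_matrix <- function(results, direction = c("up", "down")) {
  direction <- match.arg(direction)
  r <- results[results$direction == direction, , drop = FALSE]
  if (nrow(r) == 0L) stop("no results for direction '", direction, "'", call. = FALSE)
  key <- paste(r$feature_id, r$drug_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- r[duplicated(key), c("feature_id", "drug_id")][1L, ]
    stop(sprintf("duplicate (feature, drug, direction) rows, e.g. ('%s', '%s', '%s')",
                 dup$feature_id, dup$drug_id, direction), call. = FALSE)
  }
  feats <- unique(r$feature_id)
  drugs <- unique(r$drug_id)
  m <- matrix(0, length(feats), length(drugs), dimnames = list(feats, drugs))
  m[cbind(match(r$feature_id, feats), match(r$drug_id, drugs))] <- r$neg_log10_q
  attr(m, "n_filled") <- length(feats) * length(drugs) - nrow(r)
  m
}
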