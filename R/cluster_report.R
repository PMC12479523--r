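#' Complete-linkage hierarchical clustering with deterministic tie-breaking
#'
#' Agglomerative complete-linkage clustering on Euclidean distances between
#' the row (or column) vectors of a similarity matrix — the procedure used to
#' group compounds by their host-associated gene-signature similarity
#' profiles. At every step the pair of clusters with the smallest complete
#' linkage (maximum pairwise) distance is merged; ties are broken by the
#' lowest lexicographic pair of smallest original item indices, so the merge
#' sequence is fully deterministic even for duplicated items.
#'
#' @param mat numeric matrix with finite entries and dimnames.
#' @param axis cluster `"rows"` or `"columns"`.
#' @return an object of class `dendrogram_spec`: `merge` (hclust convention:
#'   negative = singleton, positive = earlier merge), `height` (non-decreasing
#'   complete-linkage merge heights), `order` (leaf permutation), `labels`,
#'   `method`, `dist_method`.
#' @export
cluster_items <- function(mat, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  x <- if (axis == "rows") mat else t(mat)
  if (any(!is.finite(x))) stop("matrix entries must all be finite", call. = FALSE)
  n <- nrow(x)
  labels <- rownames(x)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n < 1L) stop("nothing to cluster", call. = FALSE)
  if (n == 1L) {
    warning("single item on the chosen axis: trivial dendrogram")
    return(structure(list(merge = matrix(integer(0), 0L, 2L), height = numeric(0),
                          order = 1L, labels = labels, method = "complete",
                          dist_method = "euclidean"),
                     class = "dendrogram_spec"))
  }
  D <- as.matrix(stats::dist(x, method = "euclidean"))
  members <- as.list(seq_len(n))   # original item indices per active cluster
  ids <- -seq_len(n)               # hclust merge codes
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    act <- which(active)
    best_i <- best_j <- 0L
    best_d <- Inf
    best_key <- c(Inf, Inf)
    for (ii in seq_len(length(act) - 1L)) {
      for (jj in seq.int(ii + 1L, length(act))) {
        i <- act[ii]; j <- act[jj]
        d <- D[i, j]
        if (d > best_d) next
        key <- sort(c(min(members[[i]]), min(members[[j]])))
        if (d < best_d ||
            key[1L] < best_key[1L] ||
            (key[1L] == best_key[1L] && key[2L] < best_key[2L])) {
          best_d <- d; best_i <- i; best_j <- j; best_key <- key
        }
      }
    }
    i <- best_i; j <- best_j
    pair <- sort(c(ids[i], ids[j]))
    # hclust convention: negative (singleton) entries before positive ones
    merge[step, ] <- if (all(pair < 0) || all(pair > 0)) pair else c(pair[1L], pair[2L])
    height[step] <- best_d
    # complete-linkage update: distance to every other cluster is the max
    for (k in which(active)) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <- max(D[i, k], D[j, k])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    ids[i] <- step
    active[j] <- FALSE
  }

  leaf_order <- local({
    expand <- function(code) {
      if (code < 0L) return(-code)
      c(expand(merge[code, 1L]), expand(merge[code, 2L]))
    }
    expand(n - 1L)
  })
  structure(list(merge = merge, height = height, order = leaf_order,
                 labels = labels, method = "complete", dist_method = "euclidean"),
            class = "dendrogram_spec")
}

#' @export
print.dendrogram_spec <- function(x, ...) {
  cat(sprintf("<dendrogram_spec> %d items, %s linkage on %s distance\n",
              length(x$labels), x$method, x$dist_method))
  invisible(x)
}

#' Convert a dendrogram_spec to an hclust object
#' @param x a `dendrogram_spec`.
#' @param ... unused.
#' @return an object of class `hclust`.
#' @export
as.hclust.dendrogram_spec <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 dist.method = x$dist_method, call = match.call()),
            class = "hclust")
}

#' Cut a dendrogram into k groups
#' @param spec a `dendrogram_spec` from [cluster_items].
#' @param k number of groups.
#' @return named integer vector of group memberships.
#' @export
cut_dendrogram <- function(spec, k) {
  stopifnot(inherits(spec, "dendrogram_spec"))
  stats::cutree(as.hclust(spec), k = k)
}

#' Per-feature scatter data for one drug
#'
#' The data behind a per-drug scatter panel: one point per feature, x the
#' capped -log10(Q) of its up-direction comparison with the drug, y that of
#' its down-direction comparison. Features significant in either direction at
#' `alpha` are flagged for labeling.
#'
#' @param results data.frame from [run_screen] covering both directions.
#' @param drug_id compound to plot.
#' @param alpha significance reference (default 0.05).
#' @return data.frame with `feature_id`, `up_neg_log10_q`, `down_neg_log10_q`,
#'   `label` (logical).
#' @export
drug_scatter_data <- function(results, drug_id, alpha = 0.05) {
  r <- results[results$drug_id == drug_id, , drop = FALSE]
  if (nrow(r) == 0L) stop("unknown drug: '", drug_id, "'", call. = FALSE)
  up <- r[r$direction == "up", , drop = FALSE]
  dn <- r[r$direction == "down", , drop = FALSE]
  if (nrow(up) == 0L || nrow(dn) == 0L) {
    stop("results must cover both directions for drug '", drug_id, "'", call. = FALSE)
  }
  feats <- union(up$feature_id, dn$feature_id)
  ui <- match(feats, up$feature_id); di <- match(feats, dn$feature_id)
  out <- data.frame(
    feature_id = feats,
    up_neg_log10_q = ifelse(is.na(ui), 0, up$neg_log10_q[ui]),
    down_neg_log10_q = ifelse(is.na(di), 0, dn$neg_log10_q[di]),
    stringsAsFactors = FALSE
  )
  q_up <- ifelse(is.na(ui), 1, up$q_adj[ui])
  q_dn <- ifelse(is.na(di), 1, dn$q_adj[di])
  out$label <- q_up <= alpha | q_dn <= alpha
  out
}

#' Rank mimicry pairs
#'
#' Within each group (drug or feature) and direction, pairs are sorted by
#' ascending adjusted Q, ties broken by descending odds ratio, then by
#' lexicographic identifier; rows at `q_adj <= alpha` are flagged significant.
#'
#' @param results data.frame from [run_screen].
#' @param mode `"by_drug"` (rank features within each drug) or `"by_feature"`.
#' @param alpha significance threshold for the `significant` flag.
#' @return `results` with `rank` and `significant` columns, sorted within
#'   groups.
#' @export
rank_mimics <- function(results, mode = c("by_drug", "by_feature"), alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot("q_adj" %in% names(results))
  group <- if (mode == "by_drug") results$drug_id else results$feature_id
  other <- if (mode == "by_drug") results$feature_id else results$drug_id
  # -odds_ratio with Inf/NaN: Inf ranks first among ties, NaN last
  or_key <- results$odds_ratio
  or_key[is.nan(or_key)] <- -Inf
  o <- order(group, results$direction, results$q_adj, -or_key, other)
  out <- results[o, , drop = FALSE]
  key <- paste(if (mode == "by_drug") out$drug_id else out$feature_id, out$direction)
  out$rank <- as.integer(stats::ave(seq_len(nrow(out)), key, FUN = seq_along))
  out$significant <- out$q_adj <= alpha
  rownames(out) <- NULL
  out
}

#' Serialize a dendrogram as newick
#'
#' @param spec a `dendrogram_spec`.
#' @return single newick string (requires the `ape` package).
#' @export
dendrogram_newick <- function(spec) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the 'ape' package is required for newick serialization", call. = FALSE)
  }
  ape::write.tree(ape::as.phylo(as.hclust(spec)))
}

#' Render a clustered similarity heatmap
#'
#' Thin plotting layer over a similarity matrix: rows and columns are ordered
#' by [cluster_items] and drawn with `pheatmap` when available. All numbers
#' shown are exactly the matrix entries, which should be serialized to TSV
#' alongside any figure.
#'
#' @param mat matrix from [build_similarity_matrix].
#' @param file optional output file (png/pdf chosen by extension).
#' @param ... passed to `pheatmap::pheatmap`.
#' @return the pheatmap object, invisibly.
#' @export
plot_similarity_heatmap <- function(mat, file = NULL, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("the 'pheatmap' package is required for heatmap rendering", call. = FALSE)
  }
  row_cl <- if (nrow(mat) > 1L) as.hclust(cluster_items(mat, "rows")) else FALSE
  col_cl <- if (ncol(mat) > 1L) as.hclust(cluster_items(mat, "columns")) else FALSE
  args <- list(mat = mat, cluster_rows = row_cl, cluster_cols = col_cl, ...)
  if (!is.null(file)) args$filename <- file
  invisible(do.call(pheatmap::pheatmap, args))
}
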