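#' Catalog filter criteria
#'
#' Experimental criteria used to narrow an ingested perturbation catalog to a
#' comparable slice: a candidate compound whitelist plus a single cell line,
#' dose and timepoint. The defaults (MCF7, 10 uM, 24 h) are the most common
#' consistent screening condition in L1000-style chemical-perturbation data.
#'
#' @param drug_whitelist optional character vector of compound identifiers;
#'   `NULL` disables whitelist filtering.
#' @param cell_line cell-line identifier, or `NULL` to skip.
#' @param dose,dose_unit dose filter, or `dose = NULL` to skip.
#' @param time,time_unit timepoint filter, or `time = NULL` to skip.
#' @param signature_size optional top-N per direction used by
#'   [cut_ranked_profile] when ingesting ranked profiles.
#' @return a list of class `catalog_filter`.
#' @export
catalog_filter <- function(drug_whitelist = NULL, cell_line = "MCF7",
                           dose = 10, dose_unit = "uM",
                           time = 24, time_unit = "h",
                           signature_size = NULL) {
  if (!is.null(signature_size)) stopifnot(signature_size >= 1)
  structure(list(drug_whitelist = drug_whitelist, cell_line = cell_line,
                 dose = dose, dose_unit = dose_unit, time = time,
                 time_unit = time_unit, signature_size = signature_size),
            class = "catalog_filter")
}

#' Filter a drug-signature catalog on metadata criteria
#'
#' A pure filter: retains exactly the signatures matching every active
#' criterion, in input order, and reports the retained/total count. An empty
#' result is a hard error naming the criterion that eliminated the last
#' candidate, since a screen with no drugs is never intended.
#'
#' @param signatures list of [drug_signature] objects.
#' @param filter a [catalog_filter].
#' @return the retained sublist of `signatures`.
#' @export
filter_catalog <- function(signatures, filter = catalog_filter()) {
  stopifnot(inherits(filter, "catalog_filter"), length(signatures) > 0L)
  total <- length(signatures)
  keep <- signatures
  criteria <- list(
    whitelist = function(s) is.null(filter$drug_whitelist) ||
      s$drug_id %in% filter$drug_whitelist,
    cell_line = function(s) is.null(filter$cell_line) ||
      identical(as.character(s$cell_line), as.character(filter$cell_line)),
    dose = function(s) is.null(filter$dose) ||
      (isTRUE(all.equal(as.numeric(s$dose), as.numeric(filter$dose))) &&
         identical(as.character(s$dose_unit), as.character(filter$dose_unit))),
    timepoint = function(s) is.null(filter$time) ||
      (isTRUE(all.equal(as.numeric(s$time), as.numeric(filter$time))) &&
         identical(as.character(s$time_unit), as.character(filter$time_unit)))
  )
  for (crit in names(criteria)) {
    before <- length(keep)
    keep <- Filter(criteria[[crit]], keep)
    if (length(keep) == 0L) {
      stop(sprintf("catalog filter '%s' eliminated the last candidate (%d remained before it)",
                   crit, before), call. = FALSE)
    }
  }
  message(sprintf("filter_catalog: retained %d of %d signatures", length(keep), total))
  keep
}

#' Cut a ranked differential-expression profile into up/down sets
#'
#' For catalogs distributed as ranked z-scored profiles rather than pre-cut
#' sets: the up set is the top `signature_size` genes by descending score, the
#' down set the bottom `signature_size` by ascending score. Ties at a cut
#' boundary are broken lexicographically by gene identifier, so the output is
#' identical across runs and input orderings. Negating every score swaps the
#' two sets exactly.
#'
#' @param profile named numeric vector: gene -> differential score (finite).
#' @param signature_size genes per direction; at most `length(profile) / 2`.
#' @return list with `up` and `down` character vectors.
#' @export
cut_ranked_profile <- function(profile, signature_size) {
  stopifnot(is.numeric(profile), !is.null(names(profile)))
  if (anyNA(profile) || any(!is.finite(profile))) {
    stop("profile scores must all be finite", call. = FALSE)
  }
  if (anyDuplicated(names(profile))) {
    stop("duplicate gene identifiers in profile", call. = FALSE)
  }
  n <- length(profile)
  if (signature_size < 1 || signature_size > n / 2) {
    stop("signature_size must be in [1, |profile| / 2]", call. = FALSE)
  }
  if (max(profile) == min(profile)) {
    stop("degenerate profile: all scores equal", call. = FALSE)
  }
  g <- names(profile)
  up_order <- order(-profile, g)       # descending score, ties by gene id
  down_order <- order(profile, g)      # ascending score, ties by gene id
  list(up = g[up_order[seq_len(signature_size)]],
       down = g[down_order[seq_len(signature_size)]])
}
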