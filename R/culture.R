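#' Classify a metabolite as produced, consumed, or unchanged
#'
#' Compares replicate supernatant intensities from a cultured strain against
#' uninoculated-medium control intensities using the mean log2 fold-change
#' `log2((mean_sup + eps) / (mean_ctl + eps))`, where `eps` is half the
#' smallest nonzero intensity in the profile (a standard pseudocount for
#' intensity data with zeros). The call is `produced` when the effect is at or
#' above `log2fc_threshold`, `consumed` at or below its negative, `unchanged`
#' otherwise. No inferential test is attempted at typical replicate counts
#' (n = 3); the rule is a deliberate, transparent simplification. Swapping the
#' two arms negates the effect and maps produced to consumed exactly.
#'
#' @param supernatant numeric vector of replicate intensities (>= 0).
#' @param control numeric vector of replicate intensities from uninoculated
#'   medium (>= 0).
#' @param log2fc_threshold symmetric log2 fold-change threshold (default 1,
#'   i.e. two-fold).
#' @return list with `label` (`"produced"`, `"consumed"`, `"unchanged"`),
#'   `effect` (log2 fold-change), `flagged` (`TRUE` when both arms are all
#'   zero and the call is vacuous).
#' @export
classify_production <- function(supernatant, control, log2fc_threshold = 1) {
  stopifnot(length(supernatant) >= 1L, length(control) >= 1L, log2fc_threshold > 0)
  if (anyNA(supernatant) || anyNA(control) ||
      any(!is.finite(supernatant)) || any(!is.finite(control))) {
    stop("intensities must be finite", call. = FALSE)
  }
  if (any(supernatant < 0) || any(control < 0)) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  all_int <- c(supernatant, control)
  nonzero <- all_int[all_int > 0]
  if (length(nonzero) == 0L) {
    return(list(label = "unchanged", effect = 0, flagged = TRUE))
  }
  eps <- min(nonzero) / 2
  effect <- log2((mean(supernatant) + eps) / (mean(control) + eps))
  label <- if (effect >= log2fc_threshold) "produced"
  else if (effect <= -log2fc_threshold) "consumed"
  else "unchanged"
  list(label = label, effect = effect, flagged = FALSE)
}

#' Strain x metabolite production/consumption table
#'
#' Applies [classify_production] across a long table of culture profiles and
#' returns a label matrix suitable for heatmap rendering. Metabolites can be
#' restricted to a whitelist (e.g. the key metabolites identified by a
#' mimicry screen); whitelist entries without profiles are reported.
#'
#' @param profiles data.frame with columns `strain_id`, `metabolite_id`,
#'   `arm` (`"supernatant"` or `"control"`), `replicate`, `intensity`.
#' @param metabolite_whitelist optional character vector restricting the
#'   metabolite columns; `character(0)` yields an empty table.
#' @param log2fc_threshold passed to [classify_production].
#' @return character matrix (strains x metabolites) of labels, with the
#'   numeric effects in `attr(, "effects")`.
#' @export
producer_consumer_table <- function(profiles, metabolite_whitelist = NULL,
                                    log2fc_threshold = 1) {
  needed <- c("strain_id", "metabolite_id", "arm", "replicate", "intensity")
  missing_cols <- setdiff(needed, names(profiles))
  if (length(missing_cols)) {
    stop("profiles lack columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(profiles$arm %in% c("supernatant", "control"))) {
    stop("arm must be 'supernatant' or 'control'", call. = FALSE)
  }
  key <- paste(profiles$strain_id, profiles$metabolite_id, profiles$arm,
               profiles$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- profiles[duplicated(key), c("strain_id", "metabolite_id")][1L, ]
    stop(sprintf("duplicate profile rows for strain '%s', metabolite '%s'",
                 d$strain_id, d$metabolite_id), call. = FALSE)
  }
  mets <- unique(profiles$metabolite_id)
  if (!is.null(metabolite_whitelist)) {
    absent <- setdiff(metabolite_whitelist, mets)
    if (length(absent)) {
      warning("whitelist metabolites without profiles: ",
              paste(absent, collapse = ", "))
    }
    mets <- intersect(metabolite_whitelist, mets)
  }
  strains <- unique(profiles$strain_id)
  labels <- matrix(NA_character_, length(strains), length(mets),
                   dimnames = list(strains, mets))
  effects <- matrix(NA_real_, length(strains), length(mets),
                    dimnames = list(strains, mets))
  for (s in strains) {
    for (m in mets) {
      sub <- profiles[profiles$strain_id == s & profiles$metabolite_id == m, , drop = FALSE]
      if (nrow(sub) == 0L) next
      sup <- sub$intensity[sub$arm == "supernatant"]
      ctl <- sub$intensity[sub$arm == "control"]
      if (length(sup) == 0L || length(ctl) == 0L) {
        stop(sprintf("profile for strain '%s', metabolite '%s' lacks one arm", s, m),
             call. = FALSE)
      }
      r <- classify_production(sup, ctl, log2fc_threshold)
      labels[s, m] <- r$label
      effects[s, m] <- r$effect
    }
  }
  attr(labels, "effects") <- effects
  labels
}

#' Read culture metabolomics profiles from long TSV
#'
#' @param path TSV with columns `strain_id`, `metabolite_id`, `arm`,
#'   `replicate`, `intensity`.
#' @return data.frame of profiles.
#' @export
read_culture_profiles <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
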