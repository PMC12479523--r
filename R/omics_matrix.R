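#' Construct an omics matrix
#'
#' An `omics_matrix` is the common substrate of the pipeline: a numeric
#' samples x features matrix with unique identifiers on both axes and an
#' assay kind that determines validation rules. Expression matrices hold
#' continuous intensities, taxon matrices hold non-negative (relative)
#' abundances, metabolite matrices hold non-negative intensities. Missing
#' values are allowed as `NA` and are excluded pairwise at correlation time;
#' other non-finite values (`Inf`, `NaN`) are rejected.
#'
#' @param values numeric matrix, samples in rows, features in columns, with
#'   complete `dimnames`.
#' @param assay_kind one of `"expression"`, `"taxa"`, `"metabolite"`.
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, assay_kind = c("expression", "taxa", "metabolite")) {
  assay_kind <- match.arg(assay_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("empty matrix: at least one sample and one feature are required", call. = FALSE)
  }
  sn <- rownames(values)
  fn <- colnames(values)
  if (is.null(sn) || is.null(fn)) {
    stop("`values` must carry sample identifiers as rownames and feature identifiers as colnames",
         call. = FALSE)
  }
  dup_s <- unique(sn[duplicated(sn)])
  if (length(dup_s)) {
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  dup_f <- unique(fn[duplicated(fn)])
  if (length(dup_f)) {
    stop("duplicate feature identifiers: ", paste(dup_f, collapse = ", "), call. = FALSE)
  }
  bad <- !is.na(values) & !is.finite(values)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at sample '%s', feature '%s'", sn[idx[1L]], fn[idx[2L]]),
         call. = FALSE)
  }
  if (assay_kind == "taxa" && any(values < 0, na.rm = TRUE)) {
    stop("taxon abundances must be >= 0", call. = FALSE)
  }
  if (assay_kind == "metabolite" && any(values < 0, na.rm = TRUE)) {
    stop("metabolite intensities must be >= 0", call. = FALSE)
  }
  structure(list(values = values, assay_kind = assay_kind), class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix: %s> %d samples x %d features", x$assay_kind,
              nrow(x$values), ncol(x$values)))
  n_na <- sum(is.na(x$values))
  if (n_na > 0L) cat(sprintf(", %d missing cells", n_na))
  cat("\n")
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Sample and feature identifiers of an omics matrix
#' @param x an `omics_matrix`.
#' @return character vector of identifiers.
#' @export
sample_ids <- function(x) {
  if (inherits(x, "omics_matrix")) rownames(x$values)
  else if (is.data.frame(x)) x$sample_id
  else rownames(x)
}

#' @rdname sample_ids
#' @export
feature_ids <- function(x) colnames(x$values)

#' Numeric values of an omics matrix
#' @param x an `omics_matrix`.
#' @return the samples x features numeric matrix.
#' @export
omics_values <- function(x) x$values

delim_for <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a delimited omics matrix
#'
#' Reads a rectangular delimited text matrix (first column = row identifiers,
#' header = column identifiers) and returns a validated [omics_matrix] in
#' samples x features orientation regardless of the on-disk orientation.
#' GEO-style expression tables are genes x samples while abundance tables are
#' usually samples x taxa, so orientation is declared via `orientation` or
#' resolved with `"auto"` by matching identifiers against `sample_ids`.
#'
#' @param path file path.
#' @param assay_kind assay kind, see [omics_matrix].
#' @param orientation `"samples_by_features"`, `"features_by_samples"`, or
#'   `"auto"` (requires `sample_ids`).
#' @param sample_ids optional character vector of known sample identifiers
#'   used to resolve `orientation = "auto"`.
#' @param sep field separator; defaults to `","` for `.csv`, tab otherwise.
#' @return an [omics_matrix].
#' @export
read_omics_matrix <- function(path, assay_kind,
                              orientation = c("samples_by_features",
                                              "features_by_samples", "auto"),
                              sample_ids = NULL, sep = NULL) {
  orientation <- match.arg(orientation)
  sep <- delim_for(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, row.names = NULL,
                          comment.char = "", quote = "\"")
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("empty matrix in '", path, "'", call. = FALSE)
  }
  row_ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & col != "" & toupper(col) != "NA")
      if (length(bad)) {
        stop(sprintf("non-numeric cell at row %d, column '%s' in '%s': '%s'",
                     bad[1L], colnames(body)[j], path, col[bad[1L]]), call. = FALSE)
      }
      body[[j]] <- num
    }
  }
  m <- as.matrix(body)
  rownames(m) <- row_ids

  if (orientation == "auto") {
    if (is.null(sample_ids)) {
      stop("orientation = \"auto\" requires `sample_ids` to match against", call. = FALSE)
    }
    n_row <- length(intersect(row_ids, sample_ids))
    n_col <- length(intersect(colnames(m), sample_ids))
    if (n_row == 0L && n_col == 0L) {
      stop("cannot resolve orientation: no identifiers match `sample_ids`", call. = FALSE)
    }
    orientation <- if (n_row >= n_col) "samples_by_features" else "features_by_samples"
  }
  if (orientation == "features_by_samples") m <- t(m)
  omics_matrix(m, assay_kind)
}

#' Write an omics matrix as delimited text
#'
#' Written samples x features with a `sample_id` leading column; the format
#' round-trips through [read_omics_matrix].
#'
#' @param x an [omics_matrix].
#' @param path output path.
#' @param sep field separator; defaults by extension as in [read_omics_matrix].
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(x, path, sep = NULL) {
  stopifnot(inherits(x, "omics_matrix"))
  sep <- delim_for(path, sep)
  df <- data.frame(sample_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a sample covariate table
#'
#' A covariate table pairs sample identifiers with numeric (or 0/1) covariate
#' columns used for partial-correlation adjustment; the canonical example is a
#' Lactobacillus-dominance indicator for vaginal microbiome cohorts. Missing
#' values are tolerated at construction but rejected when a covariate is used
#' for adjustment.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param ... named numeric covariate vectors, one value per sample.
#' @return a `data.frame` of class `covariate_table`.
#' @export
covariate_table <- function(sample_id, ...) {
  covs <- list(...)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "), call. = FALSE)
  }
  if (length(covs) == 0L) stop("at least one covariate column is required", call. = FALSE)
  if (is.null(names(covs)) || any(names(covs) == "")) {
    stop("covariate columns must be named", call. = FALSE)
  }
  for (nm in names(covs)) {
    if (!is.numeric(covs[[nm]]) && !is.logical(covs[[nm]])) {
      stop("covariate '", nm, "' must be numeric or logical", call. = FALSE)
    }
    if (length(covs[[nm]]) != length(sample_id)) {
      stop("covariate '", nm, "' length does not match sample_id", call. = FALSE)
    }
  }
  out <- data.frame(sample_id = as.character(sample_id), covs,
                    check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("covariate_table", "data.frame")
  out
}

#' Read / write a covariate table
#' @param path file path (TSV/CSV, `sample_id` column required).
#' @param sep field separator, defaulting by extension.
#' @return a [covariate_table].
#' @export
read_covariate_table <- function(path, sep = NULL) {
  sep <- delim_for(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("covariate table needs a 'sample_id' column", call. = FALSE)
  do.call(covariate_table, c(list(sample_id = df$sample_id),
                             as.list(df[setdiff(names(df), "sample_id")])))
}

#' @rdname read_covariate_table
#' @param x a [covariate_table].
#' @export
write_covariate_table <- function(x, path, sep = NULL) {
  sep <- delim_for(path, sep)
  utils::write.table(x, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align matrices (and covariates) on their shared samples
#'
#' Restricts every input to the intersection of sample identifiers, in the
#' order the shared samples appear in the first input. Datasets from different
#' assays are matched on coded sample identifiers, so samples profiled on only
#' one platform are dropped (and reported). Idempotent, and invariant to the
#' sample order of the inputs.
#'
#' @param ... two or more [omics_matrix] objects (a single list also works).
#' @param covariates optional [covariate_table] aligned alongside.
#' @return a list with `matrices` (aligned inputs, names preserved),
#'   `covariates` (aligned table or `NULL`), `samples` (canonical order), and
#'   `dropped` (per input, identifiers that were removed).
#' @export
align_samples <- function(..., covariates = NULL) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1L]]) && !inherits(mats[[1L]], "omics_matrix")) {
    mats <- mats[[1L]]
  }
  inputs_n <- length(mats) + !is.null(covariates)
  if (inputs_n < 2L) stop("align_samples needs at least two inputs", call. = FALSE)
  for (m in mats) stopifnot(inherits(m, "omics_matrix"))

  id_sets <- lapply(mats, function(m) rownames(m$values))
  if (!is.null(covariates)) id_sets <- c(id_sets, list(covariates$sample_id))
  shared <- Reduce(intersect, id_sets)
  if (length(shared) == 0L) {
    counts <- vapply(id_sets, length, integer(1))
    stop("no samples shared across inputs (per-input sample counts: ",
         paste(counts, collapse = ", "), ")", call. = FALSE)
  }
  # canonical order: order of appearance in the first input
  shared <- id_sets[[1L]][id_sets[[1L]] %in% shared]

  aligned <- lapply(mats, function(m) {
    omics_matrix(m$values[shared, , drop = FALSE], m$assay_kind)
  })
  names(aligned) <- names(mats)
  dropped <- lapply(id_sets, function(ids) setdiff(ids, shared))
  cov_out <- NULL
  if (!is.null(covariates)) {
    cov_out <- covariates[match(shared, covariates$sample_id), , drop = FALSE]
    rownames(cov_out) <- NULL
    class(cov_out) <- c("covariate_table", "data.frame")
  }
  list(matrices = aligned, covariates = cov_out, samples = shared, dropped = dropped)
}
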