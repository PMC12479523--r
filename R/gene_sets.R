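#' Normalize gene identifiers
#'
#' Microarray and L1000 symbol tables differ in case and whitespace
#' conventions, so all gene identifiers entering a comparison are trimmed and
#' uppercased by default.
#'
#' @param genes character vector.
#' @param uppercase normalize case (default `TRUE`).
#' @return normalized character vector.
#' @export
normalize_genes <- function(genes, uppercase = TRUE) {
  g <- trimws(as.character(genes))
  if (uppercase) g <- toupper(g)
  g[g != ""]
}

#' Read gene sets from a GMT file
#'
#' GMT is tab-separated: set name, description, then one gene per field.
#'
#' @param path GMT file path.
#' @param uppercase apply the gene-case policy of [normalize_genes].
#' @return named list of character vectors; descriptions kept in
#'   `attr(, "descriptions")`.
#' @export
read_gmt <- function(path, uppercase = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT format error at line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)), call. = FALSE)
    }
    nms[i] <- fields[1L]
    desc[i] <- fields[2L]
    sets[[i]] <- unique(normalize_genes(fields[-(1:2)], uppercase = uppercase))
  }
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  names(sets) <- nms
  names(desc) <- nms
  attr(sets, "descriptions") <- desc
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of descriptions
#'   (defaults to `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions)) descriptions[[nm]] else "na"
    if (!nzchar(d)) d <- "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a feature gene signature
#'
#' The unit compared between the microbiome and the drug catalog: the genes
#' whose expression associates positively (`up`) or negatively (`down`) with a
#' feature (microbe abundance or metabolite level) at adjusted p <= `alpha`,
#' together with the universe of genes tested.
#'
#' @param feature_id feature identifier.
#' @param up,down character vectors of gene identifiers; must be disjoint and
#'   contained in `universe`.
#' @param universe character vector, the tested gene background.
#' @param alpha the adjusted-p threshold the sets were cut at.
#' @return an object of class `gene_signature`.
#' @export
gene_signature <- function(feature_id, up, down, universe, alpha = 0.05) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  universe <- unique(as.character(universe))
  both <- intersect(up, down)
  if (length(both)) {
    stop("up and down sets must be disjoint; shared: ",
         paste(utils::head(both, 5L), collapse = ", "), call. = FALSE)
  }
  outside <- setdiff(union(up, down), universe)
  if (length(outside)) {
    stop("signature genes outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(feature_id = feature_id, up = up, down = down,
                 universe = universe, alpha = alpha),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d up, %d down (universe %d, alpha %g)\n",
              x$feature_id, length(x$up), length(x$down), length(x$universe), x$alpha))
  invisible(x)
}

#' Construct a drug perturbation signature
#'
#' An L1000-style compound signature: genes up-/down-regulated in a cell line
#' at a stated dose and timepoint.
#'
#' @param drug_id compound identifier.
#' @param up,down character vectors of genes; shared genes are an error.
#' @param universe gene background the signature was called against.
#' @param cell_line,dose,dose_unit,time,time_unit experimental metadata; all
#'   must be non-empty.
#' @return an object of class `drug_signature`.
#' @export
drug_signature <- function(drug_id, up, down, universe,
                           cell_line = "MCF7", dose = 10, dose_unit = "uM",
                           time = 24, time_unit = "h") {
  for (fld in list(drug_id = drug_id, cell_line = cell_line, dose = dose,
                   dose_unit = dose_unit, time = time, time_unit = time_unit)) {
    if (length(fld) != 1L || is.na(fld) || !nzchar(as.character(fld))) {
      stop("drug signature metadata fields must be non-empty scalars", call. = FALSE)
    }
  }
  up <- unique(as.character(up)); down <- unique(as.character(down))
  both <- intersect(up, down)
  if (length(both)) {
    stop("up and down sets must be disjoint; shared: ",
         paste(utils::head(both, 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(drug_id = drug_id, up = up, down = down,
                 universe = unique(as.character(universe)),
                 cell_line = cell_line, dose = dose, dose_unit = dose_unit,
                 time = time, time_unit = time_unit),
            class = "drug_signature")
}

#' @export
print.drug_signature <- function(x, ...) {
  cat(sprintf("<drug_signature> %s (%s, %g %s, %g %s): %d up, %d down\n",
              x$drug_id, x$cell_line, x$dose, x$dose_unit, x$time, x$time_unit,
              length(x$up), length(x$down)))
  invisible(x)
}

#' Write paired up/down signatures as GMT
#'
#' Each signature becomes two GMT lines, `<id>_UP` and `<id>_DOWN`, the
#' pairing convention [read_drug_signatures] reads back.
#'
#' @param signatures list of [gene_signature] or [drug_signature] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signatures_gmt <- function(signatures, path) {
  sets <- list()
  for (s in signatures) {
    id <- if (inherits(s, "drug_signature")) s$drug_id else s$feature_id
    sets[[paste0(id, "_UP")]] <- s$up
    sets[[paste0(id, "_DOWN")]] <- s$down
  }
  # GMT requires >= 1 gene per line; keep empty sets with a placeholder token
  sets <- lapply(sets, function(g) if (length(g)) g else "EMPTY_SET")
  write_gmt(sets, path)
}

#' Read drug signatures from a GMT file plus a metadata sidecar
#'
#' GMT set names follow the `NAME_UP` / `NAME_DOWN` pairing convention. An
#' `_UP` line without a matching `_DOWN` (or vice versa) is kept with an empty
#' complement and a warning. A gene appearing in both directions of one drug is
#' dropped from both (with a warning), enforcing disjointness. The metadata
#' sidecar is a TSV with columns `drug_id`, `cell_line`, `dose`, `dose_unit`,
#' `time`, `time_unit`.
#'
#' @param gmt_path GMT file of paired sets.
#' @param meta_path metadata TSV path, or `NULL` to stamp defaults.
#' @param universe optional explicit gene universe; defaults to all genes
#'   appearing in the ingested catalog.
#' @return named list of [drug_signature] objects.
#' @export
read_drug_signatures <- function(gmt_path, meta_path = NULL, universe = NULL) {
  sets <- read_gmt(gmt_path)
  sets <- lapply(sets, function(g) setdiff(g, "EMPTY_SET"))
  nms <- names(sets)
  is_up <- grepl("_UP$", nms)
  is_dn <- grepl("_DOWN$", nms)
  if (any(!is_up & !is_dn)) {
    warning("ignoring gene sets without _UP/_DOWN suffix: ",
            paste(nms[!is_up & !is_dn], collapse = ", "))
  }
  ids <- unique(c(sub("_UP$", "", nms[is_up]), sub("_DOWN$", "", nms[is_dn])))
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))

  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                              check.names = FALSE, stringsAsFactors = FALSE)
    needed <- c("drug_id", "cell_line", "dose", "dose_unit", "time", "time_unit")
    missing_cols <- setdiff(needed, names(meta))
    if (length(missing_cols)) {
      stop("metadata sidecar lacks columns: ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
  }

  out <- lapply(ids, function(id) {
    up <- sets[[paste0(id, "_UP")]]
    dn <- sets[[paste0(id, "_DOWN")]]
    if (is.null(up)) {
      warning("drug '", id, "': _DOWN set without matching _UP; kept with empty up set")
      up <- character(0)
    }
    if (is.null(dn)) {
      warning("drug '", id, "': _UP set without matching _DOWN; kept with empty down set")
      dn <- character(0)
    }
    both <- intersect(up, dn)
    if (length(both)) {
      warning("drug '", id, "': ", length(both),
              " gene(s) present in both directions dropped from both")
      up <- setdiff(up, both); dn <- setdiff(dn, both)
    }
    m <- list(cell_line = "MCF7", dose = 10, dose_unit = "uM", time = 24, time_unit = "h")
    if (!is.null(meta)) {
      row <- meta[meta$drug_id == id, , drop = FALSE]
      if (nrow(row) == 0L) stop("no metadata row for drug '", id, "'", call. = FALSE)
      m <- as.list(row[1L, c("cell_line", "dose", "dose_unit", "time", "time_unit")])
    }
    drug_signature(id, up, dn, universe, cell_line = m$cell_line,
                   dose = m$dose, dose_unit = m$dose_unit,
                   time = m$time, time_unit = m$time_unit)
  })
  names(out) <- ids
  out
}

#' Write a drug metadata sidecar TSV
#' @param signatures list of [drug_signature] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_drug_metadata <- function(signatures, path) {
  df <- do.call(rbind, lapply(signatures, function(s) {
    data.frame(drug_id = s$drug_id, cell_line = s$cell_line, dose = s$dose,
               dose_unit = s$dose_unit, time = s$time, time_unit = s$time_unit,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
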