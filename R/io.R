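#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample IDs and gene symbols in the first column.
#' Duplicate gene symbols are either rejected or collapsed by the per-sample
#' median across the duplicated rows, mirroring the median aggregation applied
#' to non-unique symbols when microarray probes map to the same gene.
#'
#' @param path file path
#' @param id_policy `"error"` (default) to reject duplicate symbols, or
#'   `"median_aggregate"` to collapse them by per-sample medians.
#' @param scale_flag scale of the stored values, `"log2"` by default
#' @return an [expression_matrix()]
#' @export
read_expression_matrix <- function(path, id_policy = c("error", "median_aggregate"),
                                   scale_flag = "log2") {
  id_policy <- match.arg(id_policy)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L)
    stop("empty expression matrix in ", path)
  genes <- tab[[1L]]
  samples <- colnames(tab)[-1L]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                 genes[bad[1L]], samples[bad[2L]]))
  }
  if (anyDuplicated(genes)) {
    if (id_policy == "error")
      stop("duplicate gene symbols: ",
           paste(unique(genes[duplicated(genes)]), collapse = ", "))
    # median across duplicate rows, per sample; first-occurrence order kept
    ug <- genes[!duplicated(genes)]
    agg <- vapply(ug, function(g) {
      rows <- num[genes == g, , drop = FALSE]
      apply(rows, 2L, stats::median)
    }, numeric(length(samples)))
    # vapply returns samples x genes (or a vector when one sample)
    num <- if (length(samples) == 1L) matrix(agg, ncol = 1L) else t(agg)
    genes <- ug
  }
  dimnames(num) <- list(genes, samples)
  expression_matrix(num, scale_flag = scale_flag)
}

#' Write an expression matrix as tab-delimited text
#'
#' @param expr [expression_matrix()]
#' @param path output file
#' @param id_column name for the gene-symbol column (default "gene")
#' @export
write_expression_matrix <- function(expr, path, id_column = "gene") {
  stopifnot(is_expression_matrix(expr))
  vals <- em_values(expr)
  # %.17g keeps doubles bitwise-stable across a write/read round trip
  chr <- matrix(sprintf("%.17g", vals), nrow(vals), ncol(vals))
  tab <- data.frame(rownames(expr), chr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(tab) <- c(id_column, colnames(expr))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' Broad-dialect GMT: one set per line, `name TAB description TAB gene ...`.
#' Genes are uppercased and de-duplicated preserving first occurrence.
#'
#' @param path file path
#' @return a `GeneSetCollection`: named list of character vectors with a
#'   `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  names_ <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(names_))
    stop("duplicate gene-set names: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  descs <- vapply(fields, `[[`, character(1L), 2L)
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- names_
  names(descs) <- names_
  gene_set_collection(sets, descs)
}

#' Construct a gene-set collection
#' @param sets named list of character gene vectors
#' @param description optional named character vector of descriptions
#' @return `GeneSetCollection`
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (!length(sets) || is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("'sets' must be a non-empty uniquely named list")
  if (any(lengths(sets) == 0L))
    stop("empty gene set: ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  sets <- lapply(sets, function(g) unique(toupper(g)))
  if (is.null(description)) {
    description <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, description = description[names(sets)],
            class = c("GeneSetCollection", "list"))
}

#' Write a gene-set collection in GMT format
#' @param sets `GeneSetCollection`
#' @param path output file
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort annotation table
#'
#' Tab-delimited with header. Required columns: `sample_id`, `patient_id`,
#' `tissue` (values `tumor` / `normal_liver`). Optional columns are typed on
#' read: logical mutation/exposure flags, numeric survival fields, and the
#' lesion / region / resection keys used by the heterogeneity analyses.
#' Missing optional columns are filled with `NA`.
#'
#' @param path file path
#' @return a `data.frame` of class `CohortAnnotation`, one row per sample
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  cohort_annotation(tab)
}

#' Validate and type a cohort annotation table
#'
#' @param tab data.frame with at least `sample_id`, `patient_id`, `tissue`
#' @return typed `CohortAnnotation` data.frame
#' @export
cohort_annotation <- function(tab) {
  required <- c("sample_id", "patient_id", "tissue")
  missing_cols <- setdiff(required, colnames(tab))
  if (length(missing_cols))
    stop("annotation is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "))
  if (!all(tab$tissue %in% c("tumor", "normal_liver")))
    stop("tissue must be 'tumor' or 'normal_liver'")
  logical_cols <- c("neoadjuvant", "extra_hepatic", "mut_kras", "mut_nras",
                    "mut_braf_v600e", "mut_tp53")
  numeric_cols <- c("os_time_months", "os_event", "css_time_months", "css_event")
  char_cols <- c("lesion_id", "region_id", "resection", "resection_id",
                 "msi", "cms_label", "cris_label")
  for (cc in c(logical_cols, numeric_cols, char_cols)) {
    if (!cc %in% colnames(tab)) tab[[cc]] <- NA
  }
  for (cc in logical_cols) tab[[cc]] <- parse_flag(tab[[cc]], cc)
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    if (any(is.na(v) & !is.na(tab[[cc]]) & tab[[cc]] != ""))
      stop("non-numeric value in column ", cc)
    tab[[cc]] <- v
  }
  for (cc in char_cols) tab[[cc]] <- as.character(tab[[cc]])
  tumor <- tab$tissue == "tumor"
  if (any(tumor & (is.na(tab$patient_id) | tab$patient_id == "")))
    stop("every tumor sample must map to a patient")
  for (cc in c("os_time_months", "css_time_months")) {
    if (any(tab[[cc]] < 0, na.rm = TRUE)) stop("negative survival time in ", cc)
  }
  for (cc in c("os_event", "css_event")) {
    if (!all(tab[[cc]] %in% c(0, 1, NA))) stop(cc, " must be 0/1")
  }
  class(tab) <- c("CohortAnnotation", "data.frame")
  tab
}

parse_flag <- function(x, what) {
  if (is.logical(x)) return(x)
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  bad <- !is.na(x) & x != "" & x != "na" & x != "unknown" & is.na(out)
  if (any(bad)) stop("cannot parse boolean column ", what, ": ", x[which(bad)[1L]])
  out
}

#' Write a cohort annotation table
#' @param annot `CohortAnnotation`
#' @param path output file
#' @export
write_annotation <- function(annot, path) {
  tab <- as.data.frame(annot)
  for (cc in colnames(tab)) {
    if (is.double(tab[[cc]])) {
      tab[[cc]] <- ifelse(is.na(tab[[cc]]), NA,
                          sprintf("%.17g", tab[[cc]]))
    }
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write subtype calls with class posteriors
#'
#' @param labels named character vector, sample -> subtype call
#' @param posteriors numeric matrix, samples x classes, rows summing to 1
#'   (tolerance 1e-6), rownames matching `names(labels)`
#' @param path output file
#' @export
write_subtype_calls <- function(labels, posteriors, path) {
  if (is.null(names(labels)) || is.null(rownames(posteriors)))
    stop("labels must be named and posteriors must have sample row names")
  if (!setequal(names(labels), rownames(posteriors)))
    stop("labels and posteriors cover different samples")
  posteriors <- posteriors[names(labels), , drop = FALSE]
  rs <- rowSums(posteriors)
  if (any(abs(rs - 1) > 1e-6))
    stop("posterior rows must sum to 1: offending sample(s) ",
         paste(names(labels)[abs(rs - 1) > 1e-6], collapse = ", "))
  classes <- colnames(posteriors)[order(colnames(posteriors))]
  post_chr <- matrix(sprintf("%.17g", posteriors[, classes, drop = FALSE]),
                     nrow(posteriors), length(classes),
                     dimnames = list(NULL, classes))
  tab <- data.frame(sample_id = names(labels), call = unname(labels),
                    post_chr, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read subtype calls written by [write_subtype_calls()]
#' @param path file path
#' @return list with `labels` (named character) and `posteriors` (matrix)
#' @export
read_subtype_calls <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  labels <- stats::setNames(tab$call, tab$sample_id)
  post <- as.matrix(tab[, setdiff(colnames(tab), c("sample_id", "call")),
                        drop = FALSE])
  rownames(post) <- tab$sample_id
  list(labels = labels, posteriors = post)
}
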