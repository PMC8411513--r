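#' Parse concatenated digit runs into a count table
#'
#' Published cross-tabulations sometimes survive text extraction only as one
#' concatenated digit run per row. This parser enumerates, per row, every
#' segmentation of the run into `n_cols` non-negative integers (1-2 digits,
#' no leading zeros), then searches the cross-product of row candidates for
#' segmentations satisfying the supplied marginal constraints, pruning on
#' partial column sums.
#'
#' @param digit_runs character vector, one run per row
#' @param n_cols number of columns
#' @param row_sums optional numeric vector of known row sums (NA = unknown)
#' @param col_sums optional numeric vector of known column sums (NA = unknown)
#' @param total optional known grand total
#' @param cell_checks optional list of `list(row, col, value)` fixed cells
#' @param extra_check optional predicate on the full candidate matrix
#' @return integer matrix (rows x n_cols); an error if the constraints admit
#'   no segmentation or more than one
#' @export
parse_count_table <- function(digit_runs, n_cols, row_sums = NULL,
                              col_sums = NULL, total = NULL,
                              cell_checks = NULL, extra_check = NULL) {
  n_rows <- length(digit_runs)
  if (is.null(row_sums)) row_sums <- rep(NA_real_, n_rows)
  if (is.null(col_sums)) col_sums <- rep(NA_real_, n_cols)
  cand <- lapply(seq_len(n_rows), function(i) {
    segs <- segment_digits(digit_runs[[i]], n_cols)
    if (!is.na(row_sums[i]))
      segs <- Filter(function(s) sum(s) == row_sums[i], segs)
    if (!is.null(cell_checks)) {
      for (chk in cell_checks) {
        if (chk$row == i)
          segs <- Filter(function(s) s[chk$col] == chk$value, segs)
      }
    }
    if (!length(segs))
      stop("row ", i, ": no segmentation satisfies the row constraints")
    segs
  })

  solutions <- list()
  search <- function(i, partial_cols, rows_acc) {
    if (length(solutions) > 1L) return()
    if (i > n_rows) {
      mat <- do.call(rbind, rows_acc)
      ok <- TRUE
      if (!is.null(total)) ok <- ok && sum(mat) == total
      for (j in seq_len(n_cols)) {
        if (!is.na(col_sums[j])) ok <- ok && sum(mat[, j]) == col_sums[j]
      }
      if (ok && !is.null(extra_check)) ok <- extra_check(mat)
      if (ok) solutions[[length(solutions) + 1L]] <<- mat
      return()
    }
    for (s in cand[[i]]) {
      nc <- partial_cols + s
      feasible <- all(is.na(col_sums) | nc <= col_sums)
      if (feasible && !is.null(total) && sum(nc) > total) feasible <- FALSE
      if (feasible) search(i + 1L, nc, c(rows_acc, list(s)))
      if (length(solutions) > 1L) return()
    }
  }
  search(1L, numeric(n_cols), list())
  if (!length(solutions))
    stop("no segmentation satisfies all constraints")
  if (length(solutions) > 1L)
    stop("constraints do not identify a unique segmentation")
  matrix(as.integer(solutions[[1L]]), n_rows, n_cols)
}

# all ways to split a digit string into n non-negative integers of 1-2
# digits, disallowing leading zeros in multi-digit parts
segment_digits <- function(s, n) {
  chars <- strsplit(s, "")[[1L]]
  res <- list()
  recurse <- function(pos, parts) {
    remaining <- length(chars) - pos + 1L
    slots <- n - length(parts)
    if (slots == 0L) {
      if (remaining == 0L) res[[length(res) + 1L]] <<- parts
      return()
    }
    if (remaining < slots || remaining > 2L * slots) return()
    for (w in 1:2) {
      if (pos + w - 1L > length(chars)) break
      piece <- paste(chars[pos:(pos + w - 1L)], collapse = "")
      if (w > 1L && chars[pos] == "0") next
      recurse(pos + w, c(parts, as.numeric(piece)))
    }
  }
  recurse(1L, numeric(0))
  res
}

#' Subtype correspondence tables with CMS and CRIS
#'
#' Reads the shipped transcription of the printed LMS x CMS and LMS x CRIS
#' cross-tabulation (one concatenated digit run per LMS row covering the four
#' CMS columns followed by the five CRIS columns) and reconstructs the counts
#' with [parse_count_table()]. The constraints are the marginal sums implied
#' by the printed percentages and classification totals: 129 CMS-classified
#' and 139 CRIS-classified samples, CMS1 column 11, CMS4 column 58, the LMS1
#' CMS row 22 with 10 in CMS1, the LMS5 CMS4 cell 38, the LMS4 CRIS row
#' 45 with 31 in CRIS-C, and the 86 percent CRIS-A/B share within LMS1.
#'
#' @param path transcription file (default: the shipped fixture)
#' @return list with `cms` (5 x 4) and `cris` (5 x 5) count matrices, with
#'   LMS1-5 row names and subtype column names
#' @export
lms_concordance_counts <- function(path = system.file("extdata",
                                     "lms_cms_cris_digit_runs.tsv",
                                     package = "lmsubtype")) {
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           colClasses = "character")
  runs <- stats::setNames(tab$digit_run, tab$row)
  runs <- runs[paste0("LMS", 1:5)]
  full <- parse_count_table(
    unname(runs), n_cols = 9L,
    col_sums = c(11, NA, NA, 58, NA, NA, NA, NA, NA),
    cell_checks = list(list(row = 1L, col = 1L, value = 10),
                       list(row = 5L, col = 4L, value = 38),
                       list(row = 4L, col = 7L, value = 31)),
    extra_check = function(mat) {
      sum(mat[, 1:4]) == 129 && sum(mat[, 5:9]) == 139 &&
        sum(mat[1L, 1:4]) == 22 && sum(mat[4L, 5:9]) == 45 &&
        round(100 * sum(mat[1L, 5:6]) / sum(mat[1L, 5:9])) == 86
    })
  cms <- full[, 1:4, drop = FALSE]
  cris <- full[, 5:9, drop = FALSE]
  dimnames(cms) <- list(paste0("LMS", 1:5), paste0("CMS", 1:4))
  dimnames(cris) <- list(paste0("LMS", 1:5),
                         paste0("CRIS-", c("A", "B", "C", "D", "E")))
  list(cms = cms, cris = cris)
}

#' Headline concordance percentages from the correspondence tables
#'
#' The five cross-framework share percentages quoted alongside the
#' correspondence tables: the share of CMS4 samples in LMS5, of CMS1 samples
#' in LMS1, the CMS1 share within LMS1, the CRIS-C share within LMS4, and the
#' combined CRIS-A/B share within LMS1.
#'
#' @param counts output of [lms_concordance_counts()]
#' @return named numeric vector of percentages
#' @export
lms_concordance_shares <- function(counts = lms_concordance_counts()) {
  cms <- counts$cms
  cris <- counts$cris
  c(cms4_share_in_lms5 = 100 * cms["LMS5", "CMS4"] / sum(cms[, "CMS4"]),
    cms1_share_in_lms1 = 100 * cms["LMS1", "CMS1"] / sum(cms[, "CMS1"]),
    cms1_share_of_lms1 = 100 * cms["LMS1", "CMS1"] / sum(cms["LMS1", ]),
    cris_c_share_of_lms4 = 100 * cris["LMS4", "CRIS-C"] / sum(cris["LMS4", ]),
    cris_ab_share_of_lms1 =
      100 * sum(cris["LMS1", c("CRIS-A", "CRIS-B")]) / sum(cris["LMS1", ]))
}
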