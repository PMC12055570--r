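ASSAY_CSV_COLUMNS <- c("subject_id", "matrix", "time_min", "metabolite",
                       "isotopologue", "replicate", "area", "is_area")

KNOWN_ISOTOPOLOGUES <- c("unlabeled", "15N", "13C", "15N2", "IS")

#' Read a long-format assay CSV
#'
#' Expects the interchange schema: subject_id, matrix, time_min, metabolite,
#' isotopologue, replicate, area, is_area (UTF-8, dot decimal separator;
#' an empty area field is a missing measurement). Leading comment lines
#' beginning with \code{#} (e.g. a recorded seed) are skipped. Malformed
#' rows -- unknown metabolite or isotopologue, replicate outside 1-3,
#' negative time -- are rejected with their line numbers.
#'
#' @param path CSV file path.
#' @return Data.frame of raw peak records; rejected rows are reported via
#'   warnings and an attribute \code{"rejected"}.
#' @export
read_assay_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(x) == 0) {
    warning("empty assay file: ", path)
    empty <- stats::setNames(
      data.frame(character(), character(), numeric(), character(),
                 character(), integer(), numeric(), numeric(),
                 stringsAsFactors = FALSE), ASSAY_CSV_COLUMNS)
    return(empty)
  }
  miss <- setdiff(ASSAY_CSV_COLUMNS, names(x))
  if (length(miss)) {
    stop("schema mismatch in ", path, "; missing columns: ",
         paste(miss, collapse = ", "))
  }
  x <- x[, ASSAY_CSV_COLUMNS]
  x$time_min <- as.numeric(x$time_min)
  x$replicate <- as.integer(x$replicate)
  x$area <- as.numeric(x$area)
  x$is_area <- as.numeric(x$is_area)
  ## data lines start after the header (and any skipped comment lines)
  n_comment <- sum(startsWith(readLines(path, n = 50), "#"))
  bad <- !(x$metabolite %in% assay_metabolites()) |
    !(x$isotopologue %in% KNOWN_ISOTOPOLOGUES) |
    !(x$replicate %in% 1:3) |
    is.na(x$time_min) | x$time_min < 0
  if (any(bad)) {
    lines <- which(bad) + 1 + n_comment
    warning(sum(bad), " malformed row(s) rejected (file line ",
            paste(utils::head(lines, 10), collapse = ", "),
            if (sum(bad) > 10) ", ..." else "", ")")
  }
  out <- x[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- which(bad)
  out
}

#' Write raw peak records to the interchange CSV
#'
#' @param records Raw peak-record data.frame.
#' @param path Output path.
#' @param seed Optional seed recorded as a \code{# seed:} comment header.
#' @return \code{path}, invisibly.
#' @export
write_assay_csv <- function(records, path, seed = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  utils::write.csv(records[, ASSAY_CSV_COLUMNS], con, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Write pipeline results and curves to CSV
#'
#' @param pipeline A \code{ruf_pipeline} from [run_pipeline()].
#' @param results_path,curves_path Output paths (NULL to skip either).
#' @return Invisibly, the paths written.
#' @export
write_pipeline_csv <- function(pipeline, results_path = NULL,
                               curves_path = NULL) {
  stopifnot(inherits(pipeline, "ruf_pipeline"))
  if (!is.null(results_path)) {
    utils::write.csv(pipeline$results, results_path, row.names = FALSE,
                     na = "")
  }
  if (!is.null(curves_path)) {
    utils::write.csv(pipeline$curves, curves_path, row.names = FALSE,
                     na = "")
  }
  invisible(c(results_path, curves_path))
}
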