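#' Spontaneous-report count tables
#'
#' An AERS/FAERS-like table of report counts per (drug, symptom) pair,
#' with the margins and grand total needed by the disproportionality
#' statistics.
#'
#' @param x either a data.frame with columns `drug`, `symptom`, `count`
#'   (missing pairs are zero) or a numeric matrix with drugs as rows and
#'   symptoms as columns.
#' @return An object of class `report_counts`: list with `counts` (matrix),
#'   `drugs`, `symptoms`, `drug_margins`, `symptom_margins`, `grand_total`.
#' @export
#' @examples
#' rc <- report_counts(data.frame(drug = "lipitor", symptom = "nausea",
#'                                count = 20))
#' rc$grand_total
report_counts <- function(x) {
  if (is.data.frame(x)) {
    need <- c("drug", "symptom", "count")
    if (!all(need %in% names(x))) {
      stop("report counts need columns ", paste(need, collapse = ", "))
    }
    x$drug <- normalize_text(x$drug)
    x$symptom <- normalize_text(x$symptom)
    x$count <- as.numeric(x$count)
    if (any(is.na(x$count) | x$count < 0)) {
      stop("report counts must be non-negative")
    }
    m <- stats::xtabs(count ~ drug + symptom, data = x)
    m <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  } else if (is.matrix(x)) {
    if (any(is.na(x) | x < 0)) stop("report counts must be non-negative")
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop("count matrix needs drug rownames and symptom colnames")
    }
    m <- x
  } else {
    stop("x must be a data.frame or matrix")
  }
  structure(list(counts = m,
                 drugs = rownames(m),
                 symptoms = colnames(m),
                 drug_margins = rowSums(m),
                 symptom_margins = colSums(m),
                 grand_total = sum(m)),
            class = "report_counts")
}

#' @export
print.report_counts <- function(x, ...) {
  cat("Report counts: ", length(x$drugs), " drugs x ", length(x$symptoms),
      " symptoms, ", format(x$grand_total), " reports\n", sep = "")
  invisible(x)
}

#' Read/write spontaneous-report counts (CSV: drug, symptom, count)
#'
#' @param path CSV file path.
#' @return [report_counts()] for the reader; `path` for the writer.
#' @export
read_report_counts <- function(path) {
  if (!file.exists(path)) stop("report counts file not found: ", path)
  report_counts(utils::read.csv(path, strip.white = TRUE))
}

#' @rdname read_report_counts
#' @param rc a [report_counts()] object.
#' @export
write_report_counts <- function(rc, path) {
  stopifnot(inherits(rc, "report_counts"))
  idx <- which(rc$counts > 0, arr.ind = TRUE)
  df <- data.frame(drug = rc$drugs[idx[, 1]],
                   symptom = rc$symptoms[idx[, 2]],
                   count = rc$counts[idx])
  df <- df[order(df$drug, df$symptom), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Known-ADR label sets
#'
#' A SIDER-like binary reference: the set of (drug, symptom) pairs listed as
#' known adverse reactions, used as positive labels when scoring a ranking
#' with AUC and F score.
#'
#' @param x data.frame with columns `drug` and `symptom`.
#' @return An object of class `label_set` (a de-duplicated data.frame).
#' @export
label_set <- function(x) {
  stopifnot(is.data.frame(x))
  if (!all(c("drug", "symptom") %in% names(x))) {
    stop("label set needs columns drug, symptom")
  }
  df <- data.frame(drug = normalize_text(x$drug),
                   symptom = normalize_text(x$symptom))
  df <- unique(df[order(df$drug, df$symptom), , drop = FALSE])
  rownames(df) <- NULL
  structure(df, class = c("label_set", "data.frame"))
}

#' Read/write a known-ADR label set (CSV: drug, symptom)
#'
#' @param path CSV file path.
#' @export
read_label_set <- function(path) {
  if (!file.exists(path)) stop("label set file not found: ", path)
  label_set(utils::read.csv(path, strip.white = TRUE))
}

#' @rdname read_label_set
#' @param labels a [label_set()].
#' @export
write_label_set <- function(labels, path) {
  utils::write.csv(as.data.frame(labels), path, row.names = FALSE)
  invisible(path)
}
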