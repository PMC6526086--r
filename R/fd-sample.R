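#' Irregular functional / longitudinal samples
#'
#' An `fd_sample` holds repeated-measures data in long format: one record per
#' observation `(subject, time, value)`, on a common closed domain
#' `[a, b]`.  Designs may be irregular: the number of observations per
#' subject may vary and time points may differ between subjects.  Times are
#' stored in the order supplied; no sorting is applied, and all downstream
#' computations are invariant to within-subject observation order.
#' Duplicate time points within a subject are permitted.
#'
#' @param subject vector of subject identifiers (coerced to character).
#' @param time numeric vector of observation times.
#' @param value numeric vector of responses.
#' @param domain numeric length-2 vector `c(a, b)` with `a < b`.  Defaults to
#'   the observed time range.
#' @return an object of class `fd_sample`: a list with elements `data`
#'   (a tibble with columns `subject`, `time`, `value`) and `domain`.
#' @examples
#' s <- fd_sample(c("A", "A", "B"), c(0, 0.5, 0.2), c(1.2, 0.8, -0.1))
#' n_subjects(s)
#' @export
fd_sample <- function(subject, time, value, domain = NULL) {
  if (length(subject) != length(time) || length(time) != length(value)) {
    stop_covgof("subject, time and value must have equal length",
                "covgof_format_error")
  }
  if (length(time) == 0 && is.null(domain)) {
    stop_covgof("empty input: no observations", "covgof_empty_error")
  }
  time <- as.numeric(time)
  value <- as.numeric(value)
  if (anyNA(time) || anyNA(value)) {
    stop_covgof("non-numeric or missing time/value entries",
                "covgof_parse_error")
  }
  if (is.null(domain)) domain <- range(time)
  domain <- as.numeric(domain)
  if (length(domain) != 2 || !all(is.finite(domain)) || domain[1] >= domain[2]) {
    stop_covgof("domain must be c(a, b) with a < b", "covgof_domain_error")
  }
  if (any(time < domain[1] | time > domain[2])) {
    stop_covgof("observation times outside the domain", "covgof_domain_error")
  }
  out <- list(
    data = tibble::tibble(
      subject = as.character(subject),
      time = time,
      value = value
    ),
    domain = domain
  )
  class(out) <- "fd_sample"
  out
}

#' @export
print.fd_sample <- function(x, ...) {
  m <- subject_sizes(x)
  cat(sprintf(
    "<fd_sample> %d subjects, %d observations on [%g, %g]\n",
    length(m), sum(m), x$domain[1], x$domain[2]
  ))
  if (length(m) > 0) {
    cat(sprintf("  observations per subject: %d-%d (median %g)\n",
                min(m), max(m), stats::median(m)))
  }
  invisible(x)
}

#' Number of subjects / observations in a sample
#'
#' @param x an `fd_sample`.
#' @return `n_subjects()`: the number of distinct subjects;
#'   `n_obs()`: the total observation count; `subject_sizes()`: a named
#'   integer vector of per-subject observation counts, in order of first
#'   appearance.
#' @export
n_subjects <- function(x) length(subject_sizes(x))

#' @rdname n_subjects
#' @export
n_obs <- function(x) nrow(x$data)

#' @rdname n_subjects
#' @export
subject_sizes <- function(x) {
  ids <- x$data$subject
  tab <- table(factor(ids, levels = unique(ids)))
  stats::setNames(as.integer(tab), names(tab))
}

# Split into a list of per-subject records, preserving order of first
# appearance and within-subject order.
fd_split <- function(x) {
  ids <- x$data$subject
  f <- factor(ids, levels = unique(ids))
  idx <- split(seq_along(ids), f)
  lapply(idx, function(i) {
    list(id = ids[i[1]], times = x$data$time[i], values = x$data$value[i])
  })
}

#' Read a long-format CSV into an `fd_sample`
#'
#' The file must contain a header row with (at least) a subject identifier,
#' a numeric time and a numeric value column.  Rows are grouped by subject;
#' subject order and within-subject observation order follow the file.
#'
#' @param path path to a CSV file (UTF-8, header row required).
#' @param columns named character vector mapping the roles `subject`,
#'   `time` and `value` to column names in the file.
#' @param domain optional domain override `c(a, b)`; defaults to the
#'   observed time range.
#' @return an [fd_sample].
#' @export
read_long_csv <- function(path,
                          columns = c(subject = "subject", time = "time",
                                      value = "value"),
                          domain = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- unname(columns[c("subject", "time", "value")])
  if (anyNA(need)) {
    stop_covgof("`columns` must name subject, time and value",
                "covgof_format_error")
  }
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop_covgof(paste0("missing columns: ", paste(missing_cols, collapse = ", ")),
                "covgof_format_error")
  }
  if (nrow(df) == 0) {
    stop_covgof("empty input file", "covgof_empty_error")
  }
  tvec <- suppressWarnings(as.numeric(df[[columns[["time"]]]]))
  vvec <- suppressWarnings(as.numeric(df[[columns[["value"]]]]))
  if (anyNA(tvec) || anyNA(vvec)) {
    stop_covgof("non-numeric time or value cells", "covgof_parse_error")
  }
  fd_sample(df[[columns[["subject"]]]], tvec, vvec, domain = domain)
}

#' Write an `fd_sample` to a long-format CSV
#'
#' Columns are written as `subject,time,value` with full double precision,
#' so a read/write round trip reproduces the sample up to float formatting.
#'
#' @param sample an [fd_sample].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_long_csv <- function(sample, path) {
  stopifnot(inherits(sample, "fd_sample"))
  df <- as.data.frame(sample$data)
  df$time <- format(df$time, digits = 17, trim = TRUE, scientific = FALSE)
  df$value <- format(df$value, digits = 17, trim = TRUE, scientific = FALSE)
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop_covgof(paste0("cannot write ", path, ": ",
                                           conditionMessage(e)),
                                    "covgof_io_error")
  )
  invisible(path)
}
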