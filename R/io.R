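#' Read quantal-content traces from a file
#'
#' Reads one or more QC recordings from a CSV file or an Excel sheet.
#' Two layouts are auto-detected by header inspection:
#'
#' * **long**: columns `recording_id`, `stimulus_index`, `qc` and
#'   optionally `amplitude_pA` (the `recording_id` column may be absent for
#'   a single recording);
#' * **wide**: one column of QC values per recording, column names used as
#'   recording ids.
#'
#' Stimulus indices must be contiguous from 1 within each recording; QC
#' values must be numeric and non-negative (experimental QCs are amplitude
#' ratios and need not be integers).
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"xlsx"`; guessed from the extension by default.
#' @param sheet Sheet name or index for xlsx input.
#' @return A named list of `qc_trace` tibbles, one per recording.
#' @export
read_qc_trace <- function(path, format = NULL, sheet = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  df <- switch(format,
    csv = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading xlsx requires the readxl package", call. = FALSE)
      readxl::read_excel(path, sheet = sheet)
    },
    stop("unsupported format: ", format, call. = FALSE))
  parse_trace_table(df, src = path)
}

parse_trace_table <- function(df, src = "input") {
  nms <- tolower(names(df))
  if ("qc" %in% nms) {
    names(df) <- nms
    if (!"stimulus_index" %in% nms) {
      if ("stimulus" %in% nms) names(df)[names(df) == "stimulus"] <- "stimulus_index"
      else df$stimulus_index <- seq_len(nrow(df))
    }
    if (!"recording_id" %in% names(df)) df$recording_id <- "recording_1"
    if (!is.numeric(df$qc)) {
      bad <- which(is.na(suppressWarnings(as.numeric(df$qc))))[1]
      stop(sprintf("non-numeric QC value in %s at row %d", src, bad),
           call. = FALSE)
    }
    out <- split(df, df$recording_id)
    traces <- lapply(names(out), function(id) {
      d <- dplyr::arrange(out[[id]], .data$stimulus_index)
      if (!identical(as.integer(d$stimulus_index), seq_len(nrow(d))))
        stop(sprintf("recording %s in %s: stimulus_index not contiguous from 1 (first gap near row %d)",
                     id, src,
                     which(as.integer(d$stimulus_index) != seq_len(nrow(d)))[1]),
             call. = FALSE)
      tr <- tibble::tibble(stimulus = seq_len(nrow(d)), qc = as.numeric(d$qc))
      if ("amplitude_pa" %in% names(d)) tr$amplitude <- as.numeric(d$amplitude_pa)
      new_qc_trace(tr, recording_id = id)
    })
    names(traces) <- names(out)
    return(traces)
  }
  # wide layout: every column numeric, one recording per column
  if (all(vapply(df, is.numeric, logical(1))) && ncol(df) >= 1) {
    traces <- lapply(names(df), function(id) {
      v <- df[[id]]
      v <- v[!is.na(v)]
      new_qc_trace(tibble::tibble(stimulus = seq_along(v), qc = as.numeric(v)),
                   recording_id = id)
    })
    names(traces) <- names(df)
    return(traces)
  }
  stop("could not detect trace layout in ", src,
       ": need a `qc` column (long) or all-numeric columns (wide)",
       call. = FALSE)
}

#' Write quantal-content traces to CSV
#'
#' Writes traces in the long layout read back by [read_qc_trace()]
#' (`recording_id`, `stimulus_index`, `qc`, optionally `amplitude_pA`),
#' with enough digits for a lossless round trip.
#'
#' @param traces A single `qc_trace` or a named list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_qc_trace <- function(traces, path) {
  if (inherits(traces, "qc_trace")) {
    id <- attr(traces, "recording_id")
    traces <- stats::setNames(list(traces),
                              if (is.null(id)) "recording_1" else id)
  }
  rows <- purrr::imap(traces, function(tr, id) {
    out <- tibble::tibble(recording_id = id,
                          stimulus_index = tr$stimulus,
                          qc = tr$qc)
    if ("amplitude" %in% names(tr)) out$amplitude_pA <- tr$amplitude
    out
  })
  df <- dplyr::bind_rows(rows)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
           format(x, digits = 15, trim = TRUE))
  })
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
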