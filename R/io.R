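ipd_numeric_cols <- function() {
  c("age", "male", "bmi", "off_baseline", efficacy_endpoints(),
    safety_endpoints())
}

check_ipd <- function(data, require_endpoints = character(0)) {
  required <- c("arm", "age", "male", "bmi", "off_baseline",
                require_endpoints)
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    rlang::abort(paste0("IPD table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  lv <- unique(as.character(data$arm))
  if (!length(lv) || !all(lv %in% c("active", "anchor"))) {
    rlang::abort('`arm` must take only the levels "active" and "anchor"')
  }
  invisible(data)
}

#' Read or write an IPD trial table as CSV
#'
#' The documented header is: `id`, `arm` (active/anchor), `center`, the
#' baseline covariates `age`, `male` (0/1), `bmi`, `off_baseline`, any of
#' the endpoint-change columns, and the 0/1 safety flags `ae`, `sae`,
#' `dcae`. Header matching is case-insensitive and order-free; missing
#' required columns, non-numeric entries (reported with their row number)
#' and non-binary safety flags are rejected.
#'
#' @param path CSV path.
#' @param ipd A patient-level tibble.
#' @return `read_ipd()` returns a typed, validated tibble; `write_ipd()`
#'   returns `path` invisibly.
#' @export
read_ipd <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  names(raw) <- tolower(names(raw))
  known <- c("id", "arm", "center", ipd_numeric_cols())
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    rlang::abort(paste0("unexpected column(s) in IPD file: ",
                        paste(extra, collapse = ", ")))
  }
  required <- c("arm", "age", "male", "bmi", "off_baseline")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    rlang::abort(paste0("IPD file is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }

  out <- raw
  for (cl in intersect(ipd_numeric_cols(), names(raw))) {
    vals <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(vals) & !is.na(raw[[cl]]))
    if (length(bad)) {
      rlang::abort(sprintf("non-numeric value in column `%s` at data row %s",
                           cl, paste(bad, collapse = ", ")))
    }
    out[[cl]] <- vals
  }
  for (cl in intersect(c("male", safety_endpoints()), names(out))) {
    ok <- out[[cl]] %in% c(0, 1) | is.na(out[[cl]])
    if (!all(ok)) {
      rlang::abort(sprintf("column `%s` must be 0/1; offending row %s",
                           cl, paste(which(!ok), collapse = ", ")))
    }
    out[[cl]] <- as.integer(out[[cl]])
  }
  out$arm <- factor(tolower(out$arm), levels = c("anchor", "active"))
  if (anyNA(out$arm)) {
    rlang::abort('`arm` entries must be "active" or "anchor"')
  }
  if ("center" %in% names(out)) {
    lev <- unique(out$center)
    lev <- if (!anyNA(suppressWarnings(as.numeric(lev)))) {
      as.character(sort(as.numeric(lev)))
    } else sort(lev)
    out$center <- factor(out$center, levels = lev)
  }
  if (!"id" %in% names(out)) out$id <- sprintf("pt%04d", seq_len(nrow(out)))
  check_ipd(out)
  out
}

#' @rdname read_ipd
#' @export
write_ipd <- function(ipd, path) {
  readr::write_csv(ipd, path)
  invisible(path)
}
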