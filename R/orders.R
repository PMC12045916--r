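#' @name orders
#' @title Radiology order records
#'
#' @description
#' An order table is a plain `data.frame` with one row per imaging study and
#' the canonical columns:
#'
#' * `scan_id`, `patient_id` — opaque identifiers;
#' * `exam_date` — ISO 8601 calendar date;
#' * `cpt_codes` — one or more CPT codes, semicolon-separated within the cell;
#' * `setting` — one of `outpatient`, `ed`, `inpatient`;
#' * `procedure_name` — standardized radiology procedure text (may be empty);
#' * `reason_for_exam`, `clinical_history` — clinician free text (may be empty);
#' * `sampling_weight` — positive survey weight (defaults to 1);
#' * `lcs_eligible` — optional externally supplied eligibility flag;
#' * `gold_label` — optional chart-review label: `screening`,
#'   `non_screening`, or `unknown`.
NULL

ORDER_COLUMNS <- c("scan_id", "patient_id", "exam_date", "cpt_codes",
                   "setting", "procedure_name", "reason_for_exam",
                   "clinical_history", "sampling_weight", "lcs_eligible",
                   "gold_label")
REQUIRED_COLUMNS <- c("scan_id", "patient_id", "exam_date", "cpt_codes",
                      "setting")
SETTINGS <- c("outpatient", "ed", "inpatient")
GOLD_LEVELS <- c("screening", "non_screening", "unknown")

split_cpt <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE),
         function(v) sort(unique(trimws(v[nzchar(trimws(v))]))))
}

#' Read radiology orders from a delimited text file
#'
#' Reads a header-and-rows delimited file into the canonical order table
#' (see [orders]). Foreign column headers are adapted through `mapping`;
#' absent optional columns get defaults (`procedure_name`/free text: empty;
#' `sampling_weight`: 1; `gold_label`: `"unknown"`). All row-level problems
#' (bad date, non-positive weight, unknown setting, empty CPT cell, bad gold
#' label) are collected and reported together with their row numbers rather
#' than dropped silently.
#'
#' @param path Path to the file.
#' @param mapping Optional named character vector or list mapping canonical
#'   column names to the file's header names, e.g.
#'   `c(scan_id = "AccessionNo")`.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return A `data.frame` with the canonical order columns, one row per
#'   input row.
#' @export
read_orders <- function(path, mapping = NULL, delim = ",") {
  if (!file.exists(path)) stop("orders file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           fileEncoding = "UTF-8", na.strings = NULL)
  if (!is.null(mapping)) {
    mapping <- unlist(mapping)
    bad <- setdiff(names(mapping), ORDER_COLUMNS)
    if (length(bad))
      stop("column mapping names unknown order fields: ",
           paste(bad, collapse = ", "))
    missing_src <- setdiff(unname(mapping), names(raw))
    if (length(missing_src))
      stop("mapped column(s) absent from file: ",
           paste(missing_src, collapse = ", "))
    for (canon in names(mapping))
      names(raw)[names(raw) == mapping[[canon]]] <- canon
  }
  missing_req <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(missing_req))
    stop("missing required column(s): ", paste(missing_req, collapse = ", "))

  n <- nrow(raw)
  blank_to <- function(col, default) {
    if (!col %in% names(raw)) return(rep(default, n))
    x <- raw[[col]]
    x[is.na(x)] <- default
    x
  }
  orders <- data.frame(
    scan_id = raw$scan_id,
    patient_id = raw$patient_id,
    exam_date = raw$exam_date,
    cpt_codes = raw$cpt_codes,
    setting = tolower(trimws(raw$setting)),
    procedure_name = blank_to("procedure_name", ""),
    reason_for_exam = blank_to("reason_for_exam", ""),
    clinical_history = blank_to("clinical_history", ""),
    sampling_weight = suppressWarnings(
      as.numeric(blank_to("sampling_weight", "1"))),
    lcs_eligible = if ("lcs_eligible" %in% names(raw))
      as.logical(toupper(raw$lcs_eligible)) else rep(NA, n),
    gold_label = blank_to("gold_label", "unknown"),
    stringsAsFactors = FALSE
  )
  orders$gold_label[!nzchar(orders$gold_label)] <- "unknown"

  problems <- character()
  flag <- function(bad, what) {
    if (any(bad)) problems <<- c(problems, paste0(
      what, " in row(s): ", paste(which(bad), collapse = ", ")))
  }
  dates <- as.Date(orders$exam_date, format = "%Y-%m-%d")
  flag(is.na(dates), "unparseable exam_date (expected YYYY-MM-DD)")
  flag(is.na(orders$sampling_weight) | orders$sampling_weight <= 0,
       "missing or non-positive sampling_weight")
  flag(!orders$setting %in% SETTINGS,
       paste0("setting not one of ", paste(SETTINGS, collapse = "/")))
  flag(lengths(split_cpt(orders$cpt_codes)) == 0L, "empty cpt_codes")
  flag(!orders$gold_label %in% GOLD_LEVELS,
       paste0("gold_label not one of ", paste(GOLD_LEVELS, collapse = "/")))
  if (length(problems))
    stop("invalid order rows in ", path, ":\n  ",
         paste(problems, collapse = "\n  "))
  orders
}

#' Write radiology orders (or classifier calls) to a delimited text file
#'
#' @param orders A data frame (canonical order table or an
#'   [classify_orders()] result merged back onto it).
#' @param path Output file path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_orders <- function(orders, path, delim = ",") {
  utils::write.table(orders, path, sep = delim, row.names = FALSE,
                     qmethod = "double", fileEncoding = "UTF-8")
  invisible(path)
}

#' Remove duplicate scans
#'
#' Orders sharing the key (`patient_id`, `exam_date`, CPT code set,
#' `procedure_name`) collapse to the first occurrence in input order; the CPT
#' set is compared order-insensitively. The key deliberately excludes
#' `scan_id` (re-extracted studies get fresh accession numbers) but keeps the
#' procedure name, so two distinct same-day studies of different type are
#' never merged.
#'
#' @param orders Canonical order table.
#' @return A list with `orders` (deduplicated, input order preserved),
#'   `n_removed`, and `removed_scan_ids`.
#' @export
dedup_orders <- function(orders) {
  if (nrow(orders) == 0L)
    return(list(orders = orders, n_removed = 0L,
                removed_scan_ids = character()))
  key <- paste(orders$patient_id, orders$exam_date,
               vapply(split_cpt(orders$cpt_codes), paste, character(1),
                      collapse = ";"),
               orders$procedure_name, sep = "\r")
  dup <- duplicated(key)
  list(orders = orders[!dup, , drop = FALSE],
       n_removed = sum(dup),
       removed_scan_ids = orders$scan_id[dup])
}
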