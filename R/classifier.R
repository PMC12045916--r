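CALL_LEVELS <- c("excluded", "screening", "non_screening", "unable")
EXCLUSION_REASONS <- c("none", "cpt_out_of_scope", "ed_or_inpatient",
                       "imported")

#' Scope filter: is an order an in-scope outpatient chest CT?
#'
#' Applies the exclusion cascade in order: (1) no CPT code in the lexicon's
#' in-scope set; (2) emergency-department or inpatient encounter, which is
#' typically symptom-prompted; (3) exam imported from an outside facility,
#' detected by an imported-exam marker phrase (case-insensitive) in any of the
#' three text fields.
#'
#' @param orders Canonical order table (one or more rows).
#' @param lexicon An [lcs_lexicon()].
#' @return Character vector, one of `"none"`, `"cpt_out_of_scope"`,
#'   `"ed_or_inpatient"`, `"imported"` per row.
#' @export
scope_filter <- function(orders, lexicon) {
  stopifnot(inherits(lexicon, "lcs_lexicon"))
  n <- nrow(orders)
  out <- rep("none", n)
  in_scope <- vapply(split_cpt(orders$cpt_codes),
                     function(v) any(v %in% lexicon$in_scope_cpt),
                     logical(1))
  out[!in_scope] <- "cpt_out_of_scope"
  ed_inpt <- out == "none" & orders$setting %in% c("ed", "inpatient")
  out[ed_inpt] <- "ed_or_inpatient"
  todo <- out == "none"
  if (any(todo)) {
    markers <- normalize_text(lexicon$imported_markers)
    txt <- normalize_text(paste(orders$procedure_name[todo],
                                orders$reason_for_exam[todo],
                                orders$clinical_history[todo], sep = " | "))
    imported <- Reduce(`|`, lapply(markers, function(m)
      grepl(m, txt, fixed = TRUE)), rep(FALSE, sum(todo)))
    out[todo][imported] <- "imported"
  }
  out
}

# Term hits for one order across its fields. Screening terms are sought in
# all three fields after exception masking; diagnostic and Fleischner terms
# only in the two clinician-editable free-text fields.
order_hits <- function(order, lexicon) {
  fields <- c(procedure_name = normalize_text(order$procedure_name),
              reason_for_exam = normalize_text(order$reason_for_exam),
              clinical_history = normalize_text(order$clinical_history))
  masked <- stats::setNames(mask_exceptions(fields, lexicon), names(fields))
  gather <- function(texts, terms, which_fields) {
    res <- lapply(which_fields, function(f) {
      h <- match_terms(texts[[f]], terms)
      if (nrow(h)) h$field <- f
      h
    })
    res <- res[vapply(res, nrow, integer(1)) > 0L]
    if (!length(res))
      return(data.frame(term = character(), start = integer(),
                        end = integer(), field = character(),
                        stringsAsFactors = FALSE))
    do.call(rbind, res)
  }
  free_text <- c("reason_for_exam", "clinical_history")
  list(
    screening = gather(masked, lexicon$screening_terms, names(fields)),
    diagnostic = gather(fields, lexicon$diagnostic_terms, free_text),
    fleischner = gather(fields, lexicon$fleischner_terms, free_text)
  )
}

#' Classify a single radiology order
#'
#' The four-step rule: (1) out-of-scope, ED/inpatient, or imported exams are
#' `excluded`; (2) screening terms are sought in the procedure name and both
#' free-text fields, after masking exception phrases such as "Is this
#' procedure to screen for malignancy?"; (3) diagnostic (signs/symptoms) and
#' Fleischner terms are sought in the two free-text fields; (4) any
#' diagnostic or Fleischner hit makes the order `non_screening` (a hard veto,
#' even when screening language co-occurs), otherwise any screening hit makes
#' it `screening`, otherwise it is `unable` (no term evidence either way).
#'
#' @param order A one-row canonical order table (or a list with the order
#'   fields).
#' @param lexicon An [lcs_lexicon()].
#' @return A list of class `lcs_call` with `scan_id`, `call`,
#'   `exclusion_reason`, and the three hit data frames (`screening_hits`,
#'   `diagnostic_hits`, `fleischner_hits`, each with columns `term`, `start`,
#'   `end`, `field`) justifying the call.
#' @export
classify_order <- function(order, lexicon) {
  order <- as.data.frame(order, stringsAsFactors = FALSE)
  stopifnot(nrow(order) == 1L)
  no_hits <- data.frame(term = character(), start = integer(),
                        end = integer(), field = character(),
                        stringsAsFactors = FALSE)
  reason <- scope_filter(order, lexicon)
  if (reason != "none") {
    res <- list(scan_id = order$scan_id, call = "excluded",
                exclusion_reason = reason, screening_hits = no_hits,
                diagnostic_hits = no_hits, fleischner_hits = no_hits)
    return(structure(res, class = "lcs_call"))
  }
  hits <- order_hits(order, lexicon)
  call <- if (nrow(hits$diagnostic) || nrow(hits$fleischner)) {
    "non_screening"
  } else if (nrow(hits$screening)) {
    "screening"
  } else {
    "unable"
  }
  structure(list(scan_id = order$scan_id, call = call,
                 exclusion_reason = "none",
                 screening_hits = hits$screening,
                 diagnostic_hits = hits$diagnostic,
                 fleischner_hits = hits$fleischner),
            class = "lcs_call")
}

#' @export
print.lcs_call <- function(x, ...) {
  cat("<lcs_call>", x$scan_id, "->", x$call)
  if (x$exclusion_reason != "none") cat(" (", x$exclusion_reason, ")", sep = "")
  cat("\n")
  for (nm in c("screening_hits", "diagnostic_hits", "fleischner_hits")) {
    h <- x[[nm]]
    if (nrow(h))
      cat(" ", nm, ":", paste(unique(h$term), collapse = "; "), "\n")
  }
  invisible(x)
}

#' Classify a batch of radiology orders
#'
#' Applies [classify_order()] to every row, preserving order. The result is a
#' data frame of calls with the matched terms per category (semicolon-joined
#' for file output) and carries a summary of counts per call and per
#' exclusion reason.
#'
#' @param orders Canonical order table, ideally deduplicated
#'   ([dedup_orders()]).
#' @param lexicon An [lcs_lexicon()]; defaults to the shipped lexicon.
#' @return A data frame of class `lcs_calls` with columns `scan_id`, `call`,
#'   `exclusion_reason`, `screening_terms`, `diagnostic_terms`,
#'   `fleischner_terms`; `summary(x)` or `attr(x, "summary")` gives the
#'   stage counts.
#' @examples
#' lex <- lcs_lexicon()
#' orders <- simulate_orders(sim_config(n_orders = 50, seed = 7), lex)
#' calls <- classify_orders(orders, lex)
#' summary(calls)
#' @export
classify_orders <- function(orders, lexicon = lcs_lexicon()) {
  n <- nrow(orders)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    r <- classify_order(orders[i, , drop = FALSE], lexicon)
    rows[[i]] <- data.frame(
      scan_id = r$scan_id, call = r$call,
      exclusion_reason = r$exclusion_reason,
      screening_terms = paste(unique(r$screening_hits$term), collapse = ";"),
      diagnostic_terms = paste(unique(r$diagnostic_hits$term), collapse = ";"),
      fleischner_terms = paste(unique(r$fleischner_hits$term), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  calls <- if (n) do.call(rbind, rows) else
    data.frame(scan_id = character(), call = character(),
               exclusion_reason = character(), screening_terms = character(),
               diagnostic_terms = character(), fleischner_terms = character(),
               stringsAsFactors = FALSE)
  by_call <- vapply(CALL_LEVELS, function(l) sum(calls$call == l), integer(1))
  by_reason <- vapply(EXCLUSION_REASONS, function(l)
    sum(calls$exclusion_reason == l), integer(1))
  structure(calls, class = c("lcs_calls", "data.frame"),
            summary = list(n = n, by_call = by_call,
                           by_exclusion_reason = by_reason))
}

#' @export
summary.lcs_calls <- function(object, ...) attr(object, "summary")

#' @export
print.lcs_calls <- function(x, ...) {
  s <- attr(x, "summary")
  cat("<lcs_calls>", s$n, "orders:",
      paste(sprintf("%s=%d", names(s$by_call), s$by_call), collapse = ", "),
      "\n")
  excl <- s$by_exclusion_reason[names(s$by_exclusion_reason) != "none"]
  if (any(excl > 0))
    cat("  excluded:",
        paste(sprintf("%s=%d", names(excl)[excl > 0], excl[excl > 0]),
              collapse = ", "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}
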