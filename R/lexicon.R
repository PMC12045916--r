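#' Term lexicon for lung cancer screening order classification
#'
#' Builds the lexicon of term sets the classifier matches against radiology
#' order text: screening terms, exception phrases that mask misleading
#' screening language, diagnostic (signs/symptoms) terms, Fleischner-guideline
#' spelling variants, imported-exam markers, and the in-scope CPT codes.
#' Defaults ship with the package (`inst/extdata/default_lexicon.yml`) and any
#' field can be replaced via `overrides`.
#'
#' Term syntax: a single word matches as a whole token; a trailing `-` marks a
#' token-prefix pattern (`"scr-"` matches *screen*, *screening*, *scr*, but
#' never *sarcoidosis* or *describe*); a multi-word term matches as a token
#' sequence. All matching is case-insensitive on normalized text (see
#' [normalize_text()]), under which hyphens and slashes become spaces, so
#' `"low dose"` also covers `"low-dose"`.
#'
#' @param overrides Optional named list, or path to a YAML file, whose entries
#'   replace whole lexicon fields. Allowed names: `screening_terms`,
#'   `scr_exception_phrases`, `diagnostic_terms`, `fleischner_terms`,
#'   `imported_markers`, `in_scope_cpt`, `lcs_specific_cpt`. Unknown names are
#'   an error; a field overridden to an empty set is an error.
#' @return An object of class `lcs_lexicon`: a list with the seven term-set
#'   fields plus `lexicon_version`.
#' @examples
#' lex <- lcs_lexicon()
#' lex$in_scope_cpt
#' lcs_lexicon(list(screening_terms = c("low dose")))$screening_terms
#' @export
lcs_lexicon <- function(overrides = NULL) {
  path <- system.file("extdata", "default_lexicon.yml", package = "lcscreen")
  if (!nzchar(path)) stop("default lexicon file not found in package")
  lex <- yaml::read_yaml(path)

  fields <- c("screening_terms", "scr_exception_phrases", "diagnostic_terms",
              "fleischner_terms", "imported_markers", "in_scope_cpt",
              "lcs_specific_cpt")

  if (!is.null(overrides)) {
    if (is.character(overrides) && length(overrides) == 1L) {
      if (!file.exists(overrides))
        stop("lexicon override file not found: ", overrides)
      overrides <- yaml::read_yaml(overrides)
    }
    if (!is.list(overrides))
      stop("`overrides` must be a named list or a path to a YAML file")
    unknown <- setdiff(names(overrides), fields)
    if (length(unknown))
      stop("unknown lexicon field(s) in overrides: ",
           paste(unknown, collapse = ", "))
    for (nm in names(overrides))
      lex[[nm]] <- as.character(unlist(overrides[[nm]]))
  }

  for (nm in fields) {
    lex[[nm]] <- as.character(lex[[nm]])
    if (length(lex[[nm]]) == 0L)
      stop("lexicon field '", nm, "' must not be empty")
    if (any(!nzchar(trimws(lex[[nm]]))))
      stop("lexicon field '", nm, "' contains an empty pattern")
  }
  extra <- setdiff(lex$lcs_specific_cpt, lex$in_scope_cpt)
  if (length(extra))
    stop("lcs_specific_cpt must be a subset of in_scope_cpt; not in scope: ",
         paste(extra, collapse = ", "))

  structure(lex[c("lexicon_version", fields)], class = "lcs_lexicon")
}

#' @export
print.lcs_lexicon <- function(x, ...) {
  cat("<lcs_lexicon> version", x$lexicon_version, "\n")
  for (nm in setdiff(names(x), "lexicon_version"))
    cat(sprintf("  %-22s %d: %s\n", nm, length(x[[nm]]),
                paste(utils::head(x[[nm]], 4L), collapse = ", ")))
  invisible(x)
}

#' Normalize free text for term matching
#'
#' Lowercases, maps hyphens and slashes to spaces (clinical text writes
#' "low-dose", "low dose" and "f/u" interchangeably), collapses all
#' whitespace runs to single spaces, and trims. `NA` and `NULL` become the
#' empty string. Idempotent: `normalize_text(normalize_text(x))` equals
#' `normalize_text(x)`.
#'
#' @param x Character vector (or `NULL`).
#' @return Character vector of normalized text, same length as `x`
#'   (length 1 for `NULL`).
#' @examples
#' normalize_text("LDCT  Lung\nCancer Screening")
#' @export
normalize_text <- function(x) {
  if (is.null(x) || length(x) == 0L) return("")
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- tolower(x)
  x <- gsub("[-/]", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Strip terminal sentence punctuation from a normalized exception phrase so
# "hcc screening." also matches free text that drops the period.
strip_terminal_punct <- function(x) sub("[.?!]+$", "", trimws(x))

#' Mask exception phrases so screening terms inside them cannot match
#'
#' Replaces every occurrence of each exception phrase (after applying the same
#' normalization to the phrase, ignoring its terminal punctuation) with a
#' same-length run of `#`, a character that can never match any term and that
#' breaks token runs. Spans of term hits outside masked regions therefore
#' still refer to positions in the original normalized text. Idempotent.
#'
#' @param text Character vector of normalized text (see [normalize_text()]).
#' @param lexicon An `lcs_lexicon`; its `scr_exception_phrases` are masked.
#' @return Character vector, same lengths as `text`, with phrases masked.
#' @examples
#' lex <- lcs_lexicon()
#' mask_exceptions(normalize_text("Is this procedure to screen for malignancy? No. Cough."), lex)
#' @export
mask_exceptions <- function(text, lexicon) {
  stopifnot(inherits(lexicon, "lcs_lexicon"))
  phrases <- strip_terminal_punct(normalize_text(lexicon$scr_exception_phrases))
  phrases <- phrases[nzchar(phrases)]
  vapply(text, function(tx) {
    for (ph in phrases) {
      repeat {
        at <- regexpr(ph, tx, fixed = TRUE)
        if (at == -1L) break
        substr(tx, at, at + nchar(ph) - 1L) <- strrep("#", nchar(ph))
      }
    }
    tx
  }, character(1), USE.NAMES = FALSE)
}

# Escape regex metacharacters in a literal term.
regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# Compile one lexicon term to a perl regex over normalized text.
# Tokens are maximal alnum runs; matches must not touch adjacent alnum.
term_regex <- function(term) {
  raw <- trimws(tolower(term))
  is_prefix <- grepl("-$", raw)        # detect before "-" -> " " normalization
  stem <- normalize_text(sub("-+$", "", raw))
  if (is_prefix) {
    paste0("(?<![[:alnum:]])", regex_escape(stem), "[[:alnum:]]*")
  } else {
    paste0("(?<![[:alnum:]])", regex_escape(stem), "(?![[:alnum:]])")
  }
}

#' Match lexicon terms in normalized text
#'
#' Case-insensitive matching over normalized text. Single-word terms match as
#' whole tokens, `"xyz-"` terms match any token with prefix `xyz` (the span
#' covers the whole matched token), and multi-word terms match as token
#' sequences across single spaces. Hits are returned in left-to-right order
#' with duplicate spans removed.
#'
#' @param text A single string of normalized (and, for screening terms,
#'   exception-masked) text.
#' @param terms Character vector of term patterns (lexicon syntax).
#' @return A data frame with columns `term` (the pattern that matched),
#'   `start`, `end` (1-based character offsets into `text`), zero rows if
#'   nothing matches.
#' @examples
#' lex <- lcs_lexicon()
#' match_terms(normalize_text("Annual SCREENING low-dose CT"), lex$screening_terms)
#' @export
match_terms <- function(text, terms) {
  stopifnot(length(text) == 1L)
  text <- normalize_text(text)
  hits <- list()
  for (term in terms) {
    m <- gregexpr(term_regex(term), text, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    hits[[length(hits) + 1L]] <- data.frame(
      term = term,
      start = as.integer(m),
      end = as.integer(m) + attr(m, "match.length") - 1L,
      stringsAsFactors = FALSE
    )
  }
  if (!length(hits))
    return(data.frame(term = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$end), , drop = FALSE]
  out <- out[!duplicated(out[c("start", "end")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
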