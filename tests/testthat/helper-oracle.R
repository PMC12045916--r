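# Independent brute-force oracles used by the property tests. These re-derive
# behaviour from first principles (token enumeration, direct rule reading)
# and deliberately share no code with the implementation under test.

# Normalization, re-stated independently.
oracle_norm <- function(x) {
  x <- tolower(ifelse(is.na(x), "", x))
  x <- gsub("[-/]", " ", x)
  trimws(gsub("[[:space:]]+", " ", x))
}

# Token spans: maximal alnum runs with their character offsets.
oracle_tokens <- function(text) {
  m <- gregexpr("[[:alnum:]]+", text)[[1]]
  if (m[1] == -1L) return(data.frame(tok = character(), start = integer(),
                                     end = integer()))
  data.frame(tok = regmatches(text, list(m))[[1]],
             start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L,
             stringsAsFactors = FALSE)
}

# Which terms match, by exhaustive scan: prefix terms ("x-") against every
# token; single words against every token; multi-word terms against every
# window of adjacent tokens separated by exactly one space.
oracle_match <- function(text, terms) {
  text <- oracle_norm(text)
  toks <- oracle_tokens(text)
  matched <- character()
  for (term in terms) {
    if (grepl("-$", term)) {
      stem <- oracle_norm(sub("-+$", "", term))
      if (any(startsWith(toks$tok, stem))) matched <- c(matched, term)
      next
    }
    words <- strsplit(oracle_norm(term), " ", fixed = TRUE)[[1]]
    k <- length(words)
    if (nrow(toks) < k) next
    for (i in seq_len(nrow(toks) - k + 1L)) {
      win <- toks[i:(i + k - 1L), ]
      if (!identical(win$tok, words)) next
      gaps_ok <- k == 1L ||
        all(vapply(seq_len(k - 1L), function(j)
          substr(text, win$end[j] + 1L, win$start[j + 1L] - 1L) == " ",
          logical(1)))
      if (gaps_ok) { matched <- c(matched, term); break }
    }
  }
  unique(matched)
}

# Exception masking by deletion (a different mechanism than same-length
# placeholder replacement; term *sets* must nevertheless agree).
oracle_mask <- function(text, lexicon) {
  for (ph in sub("[.?!]+$", "", oracle_norm(lexicon$scr_exception_phrases)))
    text <- gsub(ph, " @ ", text, fixed = TRUE)
  text
}

# The classification rule, re-derived directly from its decision text.
oracle_classify <- function(order, lexicon) {
  cpt <- trimws(strsplit(order$cpt_codes, ";", fixed = TRUE)[[1]])
  if (!any(cpt %in% lexicon$in_scope_cpt)) return("excluded")
  if (order$setting %in% c("ed", "inpatient")) return("excluded")
  all_text <- oracle_norm(paste(order$procedure_name, order$reason_for_exam,
                                order$clinical_history, sep = " . "))
  for (mk in oracle_norm(lexicon$imported_markers))
    if (grepl(mk, all_text, fixed = TRUE)) return("excluded")
  free_text <- oracle_norm(paste(order$reason_for_exam,
                                 order$clinical_history, sep = " . "))
  if (length(oracle_match(free_text, lexicon$diagnostic_terms)) ||
      length(oracle_match(free_text, lexicon$fleischner_terms)))
    return("non_screening")
  screening_hit <- any(vapply(
    c(order$procedure_name, order$reason_for_exam, order$clinical_history),
    function(f) length(oracle_match(oracle_mask(oracle_norm(f), lexicon),
                                    lexicon$screening_terms)) > 0L,
    logical(1)))
  if (screening_hit) "screening" else "unable"
}

# --- random-case generators -------------------------------------------------

RANDOM_VOCAB <- c("annual", "screening", "screen", "scr", "ldct", "low",
                  "dose", "lcs", "cough", "fever", "fleischner", "nodule",
                  "chest", "pain", "ct", "followup", "patient", "sarcoidosis",
                  "describe", "hcc", "malignancy", "exam", "weight", "loss",
                  "x3", "wks")

random_text <- function(n_words = sample(0:8, 1),
                        vocab = RANDOM_VOCAB,
                        exception_phrases = character()) {
  words <- sample(vocab, n_words, replace = TRUE)
  if (length(exception_phrases) && stats::runif(1) < 0.3) {
    at <- sample(seq_len(n_words + 1L), 1)
    words <- append(words, sample(exception_phrases, 1), after = at - 1L)
  }
  seps <- sample(c(" ", ", ", " - ", "  ", "/"), max(length(words) - 1L, 0),
                 replace = TRUE)
  if (!length(words)) return("")
  paste0(words, c(seps, ""), collapse = "")
}

make_order <- function(scan_id = "S1", patient_id = "P1",
                       exam_date = "2020-06-15", cpt_codes = "71250",
                       setting = "outpatient", procedure_name = "",
                       reason_for_exam = "", clinical_history = "",
                       sampling_weight = 1, lcs_eligible = NA,
                       gold_label = "unknown") {
  data.frame(scan_id = scan_id, patient_id = patient_id,
             exam_date = exam_date, cpt_codes = cpt_codes, setting = setting,
             procedure_name = procedure_name,
             reason_for_exam = reason_for_exam,
             clinical_history = clinical_history,
             sampling_weight = sampling_weight, lcs_eligible = lcs_eligible,
             gold_label = gold_label, stringsAsFactors = FALSE)
}

random_order <- function(i, lexicon) {
  make_order(
    scan_id = paste0("R", i),
    cpt_codes = sample(c("71250", "G0297", "99999", "71250;G0297"), 1),
    setting = sample(c("outpatient", "outpatient", "outpatient", "ed",
                       "inpatient"), 1),
    procedure_name = random_text(sample(0:4, 1)),
    reason_for_exam = random_text(
      exception_phrases = lexicon$scr_exception_phrases),
    clinical_history = if (stats::runif(1) < 0.2)
      paste(random_text(), sample(c("", lexicon$imported_markers), 1))
    else random_text()
  )
}
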