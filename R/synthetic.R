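# Template pools, one per true indication. Small and human-readable on
# purpose: every screening reason carries a screening term, every diagnostic
# reason a signs/symptoms term, every surveillance reason a Fleischner
# variant, and uninformative templates carry no term from any set.
SIM_TEMPLATES <- list(
  screening = list(
    procedure = c("LDCT LUNG CANCER SCREENING", "CT THORAX LDCT",
                  "CT CHEST WO CONTRAST"),
    reason = c("annual lung cancer screening", "lung cancer screening",
               "LDCT screening", "low dose CT for lung cancer screening",
               "annual LCS", "LCS baseline exam"),
    history = c("heavy smoker, due for annual screening",
                "former smoker - lung cancer screening", "")
  ),
  diagnostic = list(
    procedure = c("CT CHEST WO CONTRAST", "CT THORAX"),
    reason = c("cough x 6 weeks", "hemoptysis", "chest pain, rule out mass",
               "unintentional weight loss", "shortness of breath",
               "dyspnea on exertion", "fever and productive cough"),
    history = c("persistent cough despite antibiotics",
                "copd exacerbation with wheezing", "")
  ),
  surveillance = list(
    procedure = c("CT CHEST WO CONTRAST", "CT THORAX"),
    reason = c("nodule follow up per fleischner",
               "fleischner surveillance of 5 mm nodule",
               "pulmonary nodule, fleishner recommendations",
               "6 month fleichner follow up"),
    history = c("incidental nodule on prior imaging", "")
  ),
  uninformative = list(
    procedure = c("CT CHEST WO CONTRAST", "CT THORAX"),
    reason = c("follow up", "chest ct", "evaluate", "routine imaging",
               "per pulmonology", ""),
    history = c("see chart", "outside records reviewed", "")
  )
)

# Cross-category noise phrases used by the misleading-text mechanisms.
SIM_MISLEADING_SCREENING <- c("patient due for lung cancer screening",
                              "annual screening", "needs LDCT")
SIM_MISLEADING_SYMPTOM <- c("also reports cough", "note: chest pain",
                            "recent fatigue")

#' Configuration for the synthetic radiology-order generator
#'
#' Defaults describe the simulated order stream the package is validated on:
#' a mixture of true screening, diagnostic, nodule-surveillance, and
#' uninformative indications, with two misleading-text mechanisms. A truly
#' diagnostic order can carry only screening language in its text
#' (`misleading_screening_rate`, the false-positive mechanism: the symptom
#' lives in the chart, not the order). A truly screening order can carry
#' symptom language alongside its screening terms
#' (`misleading_symptom_rate`, the false-negative mechanism: the diagnostic
#' veto then fires).
#'
#' @param n_orders Number of orders to generate.
#' @param composition Named proportions over `screening`, `diagnostic`,
#'   `surveillance`, `uninformative`; must sum to 1 (tolerance 1e-9).
#' @param misleading_screening_rate Probability a diagnostic order's text is
#'   replaced by screening-only language.
#' @param misleading_symptom_rate Probability a screening order's text also
#'   carries a symptom phrase.
#' @param excluded_rate Probability an order is made out of scope
#'   (ED/inpatient encounter, imported-exam marker, or a non-chest-CT CPT
#'   code, chosen uniformly).
#' @param uninformative_nonscreening Probability an uninformative order's
#'   gold label is non-screening (an independent coin: their text says
#'   nothing either way).
#' @param weight_distribution Sampling-weight spec:
#'   `list(dist = "lognormal", meanlog, sdlog)` or
#'   `list(dist = "constant", value)`.
#' @param seed Integer random seed; the dataset is a pure function of the
#'   config.
#' @return A validated list of class `lcs_sim_config`.
#' @export
sim_config <- function(n_orders = 2000,
                       composition = c(screening = 0.5, diagnostic = 0.3,
                                       surveillance = 0.1,
                                       uninformative = 0.1),
                       misleading_screening_rate = 0.05,
                       misleading_symptom_rate = 0.03,
                       excluded_rate = 0.05,
                       uninformative_nonscreening = 0.7,
                       weight_distribution = list(dist = "lognormal",
                                                  meanlog = 0, sdlog = 0.5),
                       seed = 1L) {
  if (length(n_orders) != 1L || is.na(n_orders) || n_orders < 1 ||
      n_orders != round(n_orders))
    stop("n_orders must be a positive integer")
  want <- c("screening", "diagnostic", "surveillance", "uninformative")
  if (is.null(names(composition)) || !setequal(names(composition), want))
    stop("composition must be named with: ", paste(want, collapse = ", "))
  composition <- composition[want]
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9)
    stop("composition proportions must be >= 0 and sum to 1")
  rates <- c(misleading_screening_rate, misleading_symptom_rate,
             excluded_rate, uninformative_nonscreening)
  if (any(is.na(rates)) || any(rates < 0) || any(rates > 1))
    stop("all rates must lie in [0, 1]")
  if (!is.list(weight_distribution) ||
      !weight_distribution$dist %in% c("lognormal", "constant"))
    stop("weight_distribution$dist must be 'lognormal' or 'constant'")
  if (length(seed) != 1L || is.na(seed) || seed != round(seed))
    stop("seed must be a single integer")
  structure(list(n_orders = as.integer(n_orders), composition = composition,
                 misleading_screening_rate = misleading_screening_rate,
                 misleading_symptom_rate = misleading_symptom_rate,
                 excluded_rate = excluded_rate,
                 uninformative_nonscreening = uninformative_nonscreening,
                 weight_distribution = weight_distribution,
                 seed = as.integer(seed)),
            class = "lcs_sim_config")
}

draw_weights <- function(spec, n) {
  switch(spec$dist,
         lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
         constant = rep(spec$value, n))
}

#' Generate synthetic radiology orders with known gold labels
#'
#' Draws each order's true indication from the configured composition, fills
#' the three text fields from indication-specific template pools, applies the
#' misleading-text noise mechanisms, optionally knocks a fraction of orders
#' out of scope, and assigns gold labels from the generating indication -
#' never from the generated text - so noise genuinely decouples text from
#' truth. Deterministic given the config (same seed, byte-identical output).
#'
#' @param config An [sim_config()].
#' @param lexicon An [lcs_lexicon()]; used to verify that the uninformative
#'   template pool really carries no term of any set under the lexicon in
#'   force (a configuration error otherwise, since the generator's gold-label
#'   guarantees would silently break).
#' @return A canonical order table (see [orders]) with `gold_label` set, plus
#'   an `"indication"` attribute giving each row's true generating category.
#' @examples
#' orders <- simulate_orders(sim_config(n_orders = 20, seed = 42))
#' table(attr(orders, "indication"), orders$gold_label)
#' @export
simulate_orders <- function(config, lexicon = lcs_lexicon()) {
  stopifnot(inherits(config, "lcs_sim_config"))
  check_uninformative_templates(lexicon)

  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_orders
  indication <- sample(names(config$composition), n, replace = TRUE,
                       prob = config$composition)
  pick <- function(pool) pool[sample.int(length(pool), 1L)]

  procedure <- reason <- history <- gold <- character(n)
  cpt <- character(n)
  setting <- rep("outpatient", n)
  for (i in seq_len(n)) {
    tmpl <- SIM_TEMPLATES[[indication[i]]]
    procedure[i] <- pick(tmpl$procedure)
    reason[i] <- pick(tmpl$reason)
    history[i] <- pick(tmpl$history)
    gold[i] <- switch(indication[i],
      screening = "screening",
      diagnostic = ,
      surveillance = "non_screening",
      uninformative = if (stats::runif(1) < config$uninformative_nonscreening)
        "non_screening" else "screening")
    cpt[i] <- if (indication[i] == "screening" && stats::runif(1) < 0.3)
      "G0297" else "71250"

    if (indication[i] == "diagnostic" &&
        stats::runif(1) < config$misleading_screening_rate) {
      # FP mechanism: order text says screening, chart says symptoms.
      procedure[i] <- "CT CHEST WO CONTRAST"
      reason[i] <- pick(SIM_MISLEADING_SCREENING)
      history[i] <- ""
    }
    if (indication[i] == "screening" &&
        stats::runif(1) < config$misleading_symptom_rate) {
      # FN mechanism: screening order whose text also mentions symptoms.
      history[i] <- paste(history[i], pick(SIM_MISLEADING_SYMPTOM))
    }

    if (stats::runif(1) < config$excluded_rate) {
      mech <- sample.int(3L, 1L)
      if (mech == 1L) setting[i] <- pick(c("ed", "inpatient"))
      else if (mech == 2L)
        history[i] <- paste(history[i], "Exam imported from outside")
      else cpt[i] <- "71046"
    }
  }

  data_start <- as.Date("2015-08-01")
  orders <- data.frame(
    scan_id = sprintf("S%05d", seq_len(n)),
    patient_id = sprintf("P%05d", sample.int(max(1L, n %/% 2L), n,
                                             replace = TRUE)),
    exam_date = format(data_start + sample.int(2190L, n, replace = TRUE) - 1L),
    cpt_codes = cpt,
    setting = setting,
    procedure_name = procedure,
    reason_for_exam = reason,
    clinical_history = history,
    sampling_weight = draw_weights(config$weight_distribution, n),
    lcs_eligible = stats::runif(n) < 0.34,
    gold_label = gold,
    stringsAsFactors = FALSE
  )
  attr(orders, "indication") <- indication
  orders
}

# The generator's unable-to-classify guarantee holds only if uninformative
# templates stay term-free under the lexicon in force.
check_uninformative_templates <- function(lexicon) {
  tmpl <- SIM_TEMPLATES$uninformative
  texts <- normalize_text(c(tmpl$procedure, tmpl$reason, tmpl$history))
  terms <- c(lexicon$screening_terms, lexicon$diagnostic_terms,
             lexicon$fleischner_terms)
  for (tx in texts[nzchar(texts)]) {
    if (nrow(match_terms(mask_exceptions(tx, lexicon), terms)))
      stop("uninformative templates match a lexicon term under this ",
           "lexicon; gold-label guarantees would break")
  }
  invisible(TRUE)
}
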