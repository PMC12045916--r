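#' Exact Clopper-Pearson confidence interval for a binomial proportion
#'
#' Two-sided exact interval obtained by inverting the binomial test, in the
#' beta-quantile form: lower = `qbeta(a/2, k, n - k + 1)` (0 when k = 0),
#' upper = `qbeta(1 - a/2, k + 1, n - k)` (1 when k = n). Non-integer `k`/`n`
#' are accepted so the same form serves survey-weighted effective counts.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param conf Confidence level, default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' clopper_pearson(87, 90) # rounds to 91-99%
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n))
    stop("k and n must be single non-missing numbers")
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n and n >= 1")
  if (conf <= 0 || conf >= 1) stop("conf must be in (0, 1)")
  a <- 1 - conf
  lower <- if (k <= 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
  upper <- if (k >= n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Build a 2x2 contingency table of algorithm calls against gold labels
#'
#' Crosses the classifier's calls with chart-review gold labels under a
#' stated policy for unable-to-classify scans. Excluded calls and scans with
#' gold label `"unknown"` are dropped (counts are kept on the result). A
#' non-excluded call whose scan has no gold label at all is an error that
#' lists the offending `scan_id`s.
#'
#' "Screening" is the positive class: `tp` = algorithm screening and gold
#' screening, `fp` = algorithm screening and gold non-screening, `fn` and
#' `tn` analogously for algorithm non-screening.
#'
#' @param calls An [classify_orders()] result, or any data frame with
#'   `scan_id` and `call` columns.
#' @param gold A data frame with `scan_id` and `gold_label` columns (the
#'   order table itself works), or a vector of labels named by scan_id, or an
#'   unnamed vector aligned with `calls`.
#' @param policy `"exclude_unable"` (drop unable calls; the primary-analysis
#'   policy) or `"unable_as_nonscreening"` (count them as algorithm
#'   non-screening; the sensitivity-analysis policy).
#' @return An object of class `lcs_table`: list with integer `tp`, `fp`,
#'   `fn`, `tn`, `n_unable_included`, `policy`, and drop counts
#'   `n_excluded_dropped`, `n_unknown_gold_dropped`, `n_unable_dropped`.
#' @export
build_contingency <- function(calls, gold,
                              policy = c("exclude_unable",
                                         "unable_as_nonscreening")) {
  policy <- match.arg(policy)
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  if (is.data.frame(gold)) {
    idx <- match(calls$scan_id, gold$scan_id)
    glab <- gold$gold_label[idx]
  } else if (!is.null(names(gold))) {
    glab <- unname(gold[calls$scan_id])
  } else {
    if (length(gold) != nrow(calls))
      stop("unnamed gold vector must have one label per call")
    glab <- as.character(gold)
  }

  keep <- calls$call != "excluded"
  n_excl <- sum(!keep)
  missing_gold <- keep & (is.na(glab) | !nzchar(glab))
  if (any(missing_gold))
    stop("calls without a gold label for scan_id(s): ",
         paste(calls$scan_id[missing_gold], collapse = ", "))
  bad <- keep & !glab %in% GOLD_LEVELS
  if (any(bad))
    stop("invalid gold label(s) for scan_id(s): ",
         paste(calls$scan_id[bad], collapse = ", "))

  unknown <- keep & glab == "unknown"
  keep <- keep & !unknown
  call <- calls$call[keep]
  glab <- glab[keep]

  unable <- call == "unable"
  if (policy == "exclude_unable") {
    n_unable_dropped <- sum(unable)
    n_unable_included <- 0L
    call <- call[!unable]
    glab <- glab[!unable]
  } else {
    n_unable_dropped <- 0L
    n_unable_included <- sum(unable)
    call[unable] <- "non_screening"
  }

  structure(list(
    tp = sum(call == "screening" & glab == "screening"),
    fp = sum(call == "screening" & glab == "non_screening"),
    fn = sum(call == "non_screening" & glab == "screening"),
    tn = sum(call == "non_screening" & glab == "non_screening"),
    n_unable_included = n_unable_included,
    policy = policy,
    n_excluded_dropped = n_excl,
    n_unknown_gold_dropped = sum(unknown),
    n_unable_dropped = n_unable_dropped
  ), class = "lcs_table")
}

#' Construct a contingency table directly from its four cell counts
#'
#' Convenience constructor for validating against published count tables.
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts (algorithm call x
#'   gold label; screening is the positive class).
#' @param policy Unable-scan policy recorded on the table.
#' @param n_unable_included Number of unable calls folded into the
#'   non-screening row (only meaningful under `"unable_as_nonscreening"`).
#' @return An `lcs_table`.
#' @examples
#' contingency_table(tp = 87, fp = 5, fn = 3, tn = 19)
#' @export
contingency_table <- function(tp, fp, fn, tn, policy = "exclude_unable",
                              n_unable_included = 0L) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("tp, fp, fn, tn must be non-negative integers")
  if (policy == "exclude_unable" && n_unable_included != 0L)
    stop("n_unable_included must be 0 under policy exclude_unable")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 n_unable_included = as.integer(n_unable_included),
                 policy = policy, n_excluded_dropped = 0L,
                 n_unknown_gold_dropped = 0L, n_unable_dropped = 0L),
            class = "lcs_table")
}

#' @export
print.lcs_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(algorithm = c("screening", "non_screening"),
                              gold = c("screening", "non_screening")))
  cat("<lcs_table> policy:", x$policy, "\n")
  print(m)
  if (x$n_unable_included)
    cat("  includes", x$n_unable_included,
        "unable-to-classify scans as non_screening\n")
  if (x$n_unable_dropped)
    cat("  unable-to-classify scans dropped:", x$n_unable_dropped, "\n")
  invisible(x)
}

# Round half-up to whole percent, the display convention used for reports.
percent_half_up <- function(p) floor(p * 100 + 0.5)

metric_row <- function(num, den, conf) {
  if (den <= 0)
    return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                k = num, n = den, defined = FALSE))
  ci <- clopper_pearson(num, den, conf)
  list(estimate = num / den, lower = unname(ci[1]), upper = unname(ci[2]),
       k = num, n = den, defined = TRUE)
}

#' Diagnostic-accuracy metrics with exact confidence intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`, each with a
#' two-sided exact Clopper-Pearson interval. A metric with a zero denominator
#' is flagged undefined (`defined = FALSE`, estimate `NA`) rather than
#' raising an error or reporting 0/1.
#'
#' @param table An `lcs_table` (from [build_contingency()] or
#'   [contingency_table()]).
#' @param conf Confidence level, default 0.95.
#' @return An object of class `lcs_accuracy`: list of four metric entries
#'   (`sensitivity`, `specificity`, `ppv`, `npv`, each with `estimate`,
#'   `lower`, `upper`, `k`, `n`, `defined`), plus `conf`, `policy`,
#'   `weighted = FALSE`, and the source counts.
#' @examples
#' accuracy_metrics(contingency_table(87, 5, 3, 19))
#' @export
accuracy_metrics <- function(table, conf = 0.95) {
  stopifnot(inherits(table, "lcs_table"))
  counts <- c(table$tp, table$fp, table$fn, table$tn)
  if (any(counts < 0)) stop("contingency counts must be non-negative")
  structure(list(
    sensitivity = metric_row(table$tp, table$tp + table$fn, conf),
    specificity = metric_row(table$tn, table$tn + table$fp, conf),
    ppv = metric_row(table$tp, table$tp + table$fp, conf),
    npv = metric_row(table$tn, table$tn + table$fn, conf),
    conf = conf, policy = table$policy, weighted = FALSE,
    counts = c(tp = table$tp, fp = table$fp, fn = table$fn, tn = table$tn),
    not_meaningful = character()
  ), class = "lcs_accuracy")
}

#' @export
print.lcs_accuracy <- function(x, ...) {
  cat("<lcs_accuracy>", if (x$weighted) "(survey-weighted)",
      sprintf("%d%% CI, policy: %s\n", round(x$conf * 100), x$policy))
  for (nm in c("sensitivity", "specificity", "ppv", "npv")) {
    m <- x[[nm]]
    label <- sprintf("  %-12s", nm)
    if (nm %in% x$not_meaningful) {
      cat(label, "not meaningful for this comparison\n")
    } else if (!m$defined) {
      cat(label, "undefined (zero denominator)\n")
    } else {
      cat(label, sprintf("%3.0f%% (%.0f-%.0f%%)  [%.4g/%.4g]\n",
                         percent_half_up(m$estimate),
                         percent_half_up(m$lower), percent_half_up(m$upper),
                         m$k, m$n))
    }
  }
  invisible(x)
}

#' Survey-weighted diagnostic-accuracy metrics
#'
#' Each metric is a ratio of sampling-weight sums instead of counts, so the
#' point estimates refer to the source population the weights map onto. The
#' interval uses the Kish effective sample size `(sum w)^2 / sum(w^2)` of the
#' metric's denominator group, feeding effective successes
#' `p_hat * n_eff` into the exact Clopper-Pearson form. With all weights
#' equal the point estimates coincide exactly with the unweighted ones.
#'
#' @param calls,gold,policy As in [build_contingency()].
#' @param weights Positive sampling weights: a data frame with `scan_id` and
#'   `sampling_weight` (the order table works), a vector named by scan_id, or
#'   an unnamed vector aligned with `calls`.
#' @param conf Confidence level, default 0.95.
#' @return An `lcs_accuracy` with `weighted = TRUE`; `k` and `n` per metric
#'   are effective counts, not integers.
#' @export
weighted_metrics <- function(calls, gold, weights,
                             policy = c("exclude_unable",
                                        "unable_as_nonscreening"),
                             conf = 0.95) {
  policy <- match.arg(policy)
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  if (is.data.frame(weights)) {
    w <- weights$sampling_weight[match(calls$scan_id, weights$scan_id)]
  } else if (!is.null(names(weights))) {
    w <- unname(weights[calls$scan_id])
  } else {
    if (length(weights) != nrow(calls))
      stop("unnamed weights must have one entry per call")
    w <- as.numeric(weights)
  }
  if (is.data.frame(gold)) {
    glab <- gold$gold_label[match(calls$scan_id, gold$scan_id)]
  } else if (!is.null(names(gold))) {
    glab <- unname(gold[calls$scan_id])
  } else glab <- as.character(gold)

  keep <- calls$call != "excluded" & !is.na(glab) & glab != "unknown"
  if (any(keep & (is.na(w) | w <= 0)))
    stop("missing or non-positive sampling weight for scan_id(s): ",
         paste(calls$scan_id[keep & (is.na(w) | w <= 0)], collapse = ", "))
  call <- calls$call[keep]; glab <- glab[keep]; w <- w[keep]
  if (policy == "exclude_unable") {
    ok <- call != "unable"
    call <- call[ok]; glab <- glab[ok]; w <- w[ok]
    n_unable_included <- 0L
  } else {
    n_unable_included <- sum(call == "unable")
    call[call == "unable"] <- "non_screening"
  }

  cell <- function(a, g) sum(w[call == a & glab == g])
  wtp <- cell("screening", "screening")
  wfp <- cell("screening", "non_screening")
  wfn <- cell("non_screening", "screening")
  wtn <- cell("non_screening", "non_screening")

  wrow <- function(num, den_mask) {
    den <- sum(w[den_mask])
    if (den <= 0)
      return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                  k = num, n = 0, defined = FALSE))
    p <- num / den
    wd <- w[den_mask]
    n_eff <- sum(wd)^2 / sum(wd^2)             # Kish effective sample size
    ci <- clopper_pearson(p * n_eff, n_eff, conf)
    list(estimate = p, lower = unname(ci[1]), upper = unname(ci[2]),
         k = p * n_eff, n = n_eff, defined = TRUE)
  }

  structure(list(
    sensitivity = wrow(wtp, glab == "screening"),
    specificity = wrow(wtn, glab == "non_screening"),
    ppv = wrow(wtp, call == "screening"),
    npv = wrow(wtn, call == "non_screening"),
    conf = conf, policy = policy, weighted = TRUE,
    counts = c(tp = wtp, fp = wfp, fn = wfn, tn = wtn),
    not_meaningful = character()
  ), class = "lcs_accuracy")
}

#' Accuracy of administrative codes alone (the baseline the classifier beats)
#'
#' Under code-only ascertainment every in-scope chest CT counts as
#' "screening per codes", so the baseline's PPV is simply the gold-screening
#' fraction of in-scope scans. There are no code-negative scans, hence NPV is
#' undefined, and sensitivity/specificity are flagged not meaningful (all
#' studies carry a code).
#'
#' @param gold Character vector of gold labels (`screening` /
#'   `non_screening`; `unknown` is dropped) over all in-scope scans, or a
#'   data frame with a `gold_label` column.
#' @param conf Confidence level, default 0.95.
#' @return An `lcs_accuracy` with `ppv` defined and the other metrics
#'   undefined or flagged.
#' @examples
#' cpt_baseline(c(rep("screening", 101), rep("non_screening", 46)))
#' @export
cpt_baseline <- function(gold, conf = 0.95) {
  if (is.data.frame(gold)) gold <- gold$gold_label
  gold <- gold[!is.na(gold) & gold != "unknown"]
  bad <- !gold %in% c("screening", "non_screening")
  if (any(bad)) stop("invalid gold label(s): ",
                     paste(unique(gold[bad]), collapse = ", "))
  k <- sum(gold == "screening")
  n <- length(gold)
  structure(list(
    sensitivity = list(estimate = NA_real_, lower = NA_real_,
                       upper = NA_real_, k = NA_real_, n = NA_real_,
                       defined = FALSE),
    specificity = list(estimate = NA_real_, lower = NA_real_,
                       upper = NA_real_, k = NA_real_, n = NA_real_,
                       defined = FALSE),
    ppv = metric_row(k, n, conf),
    npv = list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
               k = 0, n = 0, defined = FALSE),
    conf = conf, policy = "all_in_scope_called_screening", weighted = FALSE,
    counts = c(tp = k, fp = n - k, fn = 0L, tn = 0L),
    not_meaningful = c("sensitivity", "specificity")
  ), class = "lcs_accuracy")
}

#' Compare two proportions (algorithm vs administrative-code baseline)
#'
#' Two-sample test of equal proportions via [stats::prop.test()], i.e. the
#' chi-squared test with Yates continuity correction by default, matching the
#' convention used for PPV/NPV comparisons of classifiers.
#'
#' @param k1,n1 Successes and trials for the first proportion.
#' @param k2,n2 Successes and trials for the second proportion.
#' @param correct Apply the continuity correction (default `TRUE`).
#' @return A list with `statistic` (X-squared), `p_value`, `estimate1`,
#'   `estimate2`.
#' @examples
#' compare_proportions(101, 147, 87, 92)$p_value # code PPV vs algorithm PPV
#' @export
compare_proportions <- function(k1, n1, k2, n2, correct = TRUE) {
  if (any(c(n1, n2) < 1) || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2)
    stop("need 0 <= ki <= ni and ni >= 1")
  ht <- stats::prop.test(c(k1, k2), c(n1, n2), correct = correct)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       estimate1 = k1 / n1, estimate2 = k2 / n2)
}
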