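test_that("Clopper-Pearson equals the inverted binomial test", {
  # oracle: stats::binom.test, the canonical exact-interval implementation
  set.seed(408)
  grid <- expand.grid(n = c(1, 2, 5, 10, 24, 90, 147, 500),
                      frac = c(0, 0.1, 0.5, 0.9, 1))
  for (r in seq_len(nrow(grid))) {
    n <- grid$n[r]
    k <- round(grid$frac[r] * n)
    for (conf in c(0.90, 0.95, 0.99)) {
      got <- clopper_pearson(k, n, conf)
      want <- stats::binom.test(k, n, conf.level = conf)$conf.int
      expect_equal(unname(got), as.numeric(want), tolerance = 1e-12)
      # interval always contains the point estimate
      expect_lte(got[["lower"]], k / n)
      expect_gte(got[["upper"]], k / n)
    }
  }
  expect_identical(clopper_pearson(0, 10)[["lower"]], 0)
  expect_identical(clopper_pearson(10, 10)[["upper"]], 1)
  expect_error(clopper_pearson(5, 4), "k <= n")
  expect_error(clopper_pearson(1, 0), "n >= 1")
})

test_that("interval width shrinks with n at fixed proportion", {
  widths <- vapply(c(10, 40, 160, 640), function(n) {
    ci <- clopper_pearson(round(0.8 * n), n)
    ci[["upper"]] - ci[["lower"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("95% Clopper-Pearson intervals cover the true proportion", {
  set.seed(409)
  n <- 50; p <- 0.8; reps <- 2000
  k <- stats::rbinom(reps, n, p)
  covered <- vapply(k, function(ki) {
    ci <- clopper_pearson(ki, n)
    ci[["lower"]] <= p && p <= ci[["upper"]]
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("accuracy metrics reproduce hand-computed ratios and flags", {
  rep_a <- accuracy_metrics(contingency_table(87, 5, 3, 19))
  expect_equal(rep_a$sensitivity$estimate, 87 / 90)
  expect_equal(rep_a$specificity$estimate, 19 / 24)
  expect_equal(rep_a$ppv$estimate, 87 / 92)
  expect_equal(rep_a$npv$estimate, 19 / 22)
  for (nm in c("sensitivity", "specificity", "ppv", "npv")) {
    m <- rep_a[[nm]]
    expect_true(m$defined)
    expect_true(m$lower <= m$estimate && m$estimate <= m$upper)
    # identity: estimate * denominator recovers the numerator
    expect_equal(m$estimate * m$n, as.numeric(m$k))
  }

  # all-positive degenerate table: closed-form CP lower bound (a/2)^(1/n)
  rep_d <- accuracy_metrics(contingency_table(5, 0, 0, 0))
  expect_identical(rep_d$sensitivity$estimate, 1)
  expect_equal(rep_d$sensitivity$lower, 0.025^(1 / 5), tolerance = 1e-10)
  expect_false(rep_d$specificity$defined)
  expect_false(rep_d$npv$defined)
  expect_true(rep_d$ppv$defined)
  expect_true(is.na(rep_d$specificity$estimate))
})

test_that("contingency tables cross calls with gold under both policies", {
  # calls/gold realizing: tp=87 fp=5 fn=3 tn=19, plus 33 unable (22 non-scr)
  calls <- data.frame(
    scan_id = sprintf("V%03d", 1:147),
    call = rep(c("screening", "screening", "non_screening", "non_screening",
                 "unable", "unable"),
               c(87, 5, 3, 19, 11, 22)),
    stringsAsFactors = FALSE)
  gold <- data.frame(
    scan_id = calls$scan_id,
    gold_label = rep(c("screening", "non_screening", "screening",
                       "non_screening", "screening", "non_screening"),
                     c(87, 5, 3, 19, 11, 22)),
    stringsAsFactors = FALSE)

  tab <- build_contingency(calls, gold, policy = "exclude_unable")
  expect_identical(c(tab$tp, tab$fp, tab$fn, tab$tn), c(87L, 5L, 3L, 19L))
  expect_identical(tab$n_unable_dropped, 33L)
  expect_identical(tab$n_unable_included, 0L)

  tab2 <- build_contingency(calls, gold, policy = "unable_as_nonscreening")
  expect_identical(c(tab2$tp, tab2$fp, tab2$fn, tab2$tn),
                   c(87L, 5L, 14L, 41L))
  expect_identical(tab2$n_unable_included, 33L)

  # PPV is policy-invariant; the other metrics may move
  m1 <- accuracy_metrics(tab); m2 <- accuracy_metrics(tab2)
  expect_identical(m1$ppv$estimate, m2$ppv$estimate)
  expect_lt(m2$sensitivity$estimate, m1$sensitivity$estimate)

  # excluded calls and unknown gold are dropped with counts
  calls3 <- rbind(calls[1:4, ],
                  data.frame(scan_id = c("E1", "U1"),
                             call = c("excluded", "screening")))
  gold3 <- rbind(gold[1:4, ],
                 data.frame(scan_id = c("E1", "U1"),
                            gold_label = c("screening", "unknown")))
  tab3 <- build_contingency(calls3, gold3)
  expect_identical(tab3$n_excluded_dropped, 1L)
  expect_identical(tab3$n_unknown_gold_dropped, 1L)

  # a classified call with no gold label is an error naming the scan
  gold_bad <- gold[-5, ]
  expect_error(build_contingency(calls, gold_bad), "V005")

  empty <- build_contingency(calls[0, ], gold[0, ])
  expect_identical(c(empty$tp, empty$fp, empty$fn, empty$tn),
                   c(0L, 0L, 0L, 0L))
})

test_that("weighted metrics degenerate to unweighted under equal weights", {
  lex <- lcs_lexicon()
  orders <- simulate_orders(sim_config(n_orders = 300, seed = 13), lex)
  calls <- classify_orders(orders, lex)
  unw <- accuracy_metrics(build_contingency(calls, orders))

  w1 <- stats::setNames(rep(1, nrow(orders)), orders$scan_id)
  eq <- weighted_metrics(calls, orders, w1)
  for (nm in c("sensitivity", "specificity", "ppv", "npv"))
    expect_identical(eq[[nm]]$estimate, unw[[nm]]$estimate)
  # and the CIs coincide too: n_eff equals n when weights are equal
  expect_equal(eq$sensitivity$lower, unw$sensitivity$lower, tolerance = 1e-9)

  # scale invariance of the point estimates
  sc <- weighted_metrics(calls, orders, w1 * 2)
  for (nm in c("sensitivity", "specificity", "ppv", "npv"))
    expect_identical(sc[[nm]]$estimate, unw[[nm]]$estimate)
})

test_that("weighted PPV is the weight share of the concordant scan", {
  calls <- data.frame(scan_id = c("a", "b"),
                      call = c("screening", "screening"))
  gold <- data.frame(scan_id = c("a", "b"),
                     gold_label = c("screening", "non_screening"))
  w <- c(a = 1, b = 3)
  expect_equal(weighted_metrics(calls, gold, w)$ppv$estimate, 0.25)
  expect_equal(weighted_metrics(calls, gold, rev(w))$ppv$estimate, 0.25)
  w2 <- c(a = 3, b = 1)
  expect_equal(weighted_metrics(calls, gold, w2)$ppv$estimate, 0.75)
  expect_error(weighted_metrics(calls, gold, c(a = 1, b = -1)),
               "non-positive")
})

test_that("administrative-code baseline treats every in-scope scan as screening", {
  base <- cpt_baseline(c(rep("screening", 101), rep("non_screening", 46)))
  expect_equal(base$ppv$estimate, 101 / 147)
  expect_false(base$npv$defined)
  expect_true("sensitivity" %in% base$not_meaningful)
  expect_true("specificity" %in% base$not_meaningful)
  expect_identical(cpt_baseline(rep("screening", 9))$ppv$estimate, 1)
  expect_identical(cpt_baseline(rep("non_screening", 9))$ppv$estimate, 0)
})

test_that("two-proportion comparison matches its exact-test oracle in magnitude", {
  same <- compare_proportions(10, 20, 10, 20)
  expect_equal(same$p_value, 1)

  # oracle: exact hypergeometric enumeration for the extreme 0/10 vs 10/10
  p_exact <- 2 / choose(20, 10)
  got <- compare_proportions(0, 10, 10, 10)
  expect_lt(abs(log10(got$p_value) - log10(p_exact)), 1.5)

  # continuity correction on by default, matching prop.test
  ht <- stats::prop.test(c(30, 50), c(100, 100))
  got2 <- compare_proportions(30, 100, 50, 100)
  expect_equal(got2$p_value, ht$p.value)
  expect_equal(got2$statistic, unname(ht$statistic))
  got3 <- compare_proportions(30, 100, 50, 100, correct = FALSE)
  expect_equal(got3$p_value,
               stats::prop.test(c(30, 50), c(100, 100),
                                correct = FALSE)$p.value)
  expect_error(compare_proportions(5, 4, 1, 2), "ki <= ni")
})
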