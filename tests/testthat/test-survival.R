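test_that("survival records follow the dead/alive time rules", {
  ct <- clinical_table(data.frame(
    patient_id = c("A", "B", "C", "D", "E"),
    vital_status = c("dead", "alive", "dead", NA, "alive"),
    days_to_death = c(100, NA, NA, 50, NA),
    days_to_last_follow_up = c(NA, 400, 200, 60, 0),
    t_stage = NA, n_stage = NA, m_stage = NA, grade = NA,
    pathologic_stage = NA, clinical_stage = NA))
  rec <- survival_records_quiet(ct)
  expect_equal(rec$patient_id, c("A", "B"))
  expect_equal(rec$time, c(100, 400))
  expect_equal(rec$event, c(TRUE, FALSE))
  # C (dead, no days_to_death), D (no status), E (zero time) excluded
  expect_equal(attr(rec, "n_excluded"), 3)
})

test_that("KM curve matches hand product-limit computations", {
  k <- km_curve(data.frame(time = c(1, 2, 3), event = TRUE))
  expect_equal(k$survival, c(2 / 3, 1 / 3, 0))
  # censoring between events: events at 1 and 3, censor at 2
  k2 <- km_curve(data.frame(time = c(1, 2, 3), event = c(TRUE, FALSE, TRUE)))
  expect_equal(k2$event_times, c(1, 3))
  expect_equal(k2$survival, c(2 / 3, 0))
  # all censored: no event times, curve stays at 1
  k3 <- km_curve(data.frame(time = c(4, 9), event = FALSE))
  expect_equal(length(k3$event_times), 0)
  expect_error(km_curve(data.frame(time = numeric(), event = logical())),
               "no survival records")
})

test_that("KM curve equals the enumeration oracle on all small datasets", {
  for (n in 1:5) {
    patterns <- expand.grid(rep(list(c(TRUE, FALSE)), n))
    for (i in seq_len(nrow(patterns))) {
      event <- as.logical(patterns[i, ])
      if (!any(event)) next
      time <- seq_len(n)
      k <- km_curve(data.frame(time = time, event = event))
      o <- km_oracle(time, event)
      expect_equal(k$event_times, o$time)
      expect_equal(k$survival, o$surv, tolerance = 1e-12)
      # with a death/censor tie at one time, deaths are processed first
      time2 <- pmin(time, n - 0.5)  # creates one tie for n >= 2
      k2 <- km_curve(data.frame(time = time2, event = event))
      o2 <- km_oracle(time2, event)
      expect_equal(k2$survival, o2$surv, tolerance = 1e-12)
    }
  }
})

test_that("log-rank reproduces the hand-computed 2-vs-2 table", {
  a <- data.frame(time = c(1, 2), event = TRUE)
  b <- data.frame(time = c(3, 4), event = TRUE)
  lr <- logrank_test(a, b)
  # O_A - E_A = 7/6, V = 17/36 -> chi2 = 49/17
  expect_equal(lr$chi2, 49 / 17, tolerance = 1e-9)
  expect_equal(lr$p_value, pchisq(49 / 17, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("log-rank is symmetric, order-invariant, and null on identical groups", {
  a <- data.frame(time = c(1, 5, 9, 12), event = c(TRUE, TRUE, FALSE, TRUE))
  b <- data.frame(time = c(2, 3, 8, 20), event = c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(logrank_test(a, b)$chi2, logrank_test(b, a)$chi2)
  shuffled <- a[c(3, 1, 4, 2), ]
  expect_equal(logrank_test(a, b)$chi2, logrank_test(shuffled, b)$chi2)
  same <- logrank_test(a, a)
  expect_equal(same$chi2, 0)
  expect_equal(same$p_value, 1)
  expect_error(logrank_test(a, a[0, ]), "non-empty")
})

test_that("the fully separated 2-vs-2 arrangement maximizes the statistic", {
  # all ways to split event times 1..4 into two groups of two
  splits <- combn(4, 2, simplify = FALSE)
  chi <- vapply(splits, function(s) {
    logrank_test(data.frame(time = s, event = TRUE),
                 data.frame(time = setdiff(1:4, s), event = TRUE))$chi2
  }, 1)
  extreme <- which(vapply(splits, function(s) all(s == c(1, 2)) ||
                            all(s == c(3, 4)), TRUE))
  expect_equal(which(chi >= max(chi) - 1e-9), extreme)
})

test_that("a planted prognostic gene scores 1", {
  sim <- simulate_cohort(sim_config(n_genes = 5, n_tumor = 200, n_normal = 10,
                                    frac_surv = 0.2, frac_dge = 0,
                                    frac_clinical = 0, frac_hotspot = 0,
                                    frac_dependent = 0, hazard_ratio_high = 3,
                                    censor_rate = 0.2, seed = 1))
  g <- sim$truth$gene[sim$truth$planted_surv]
  em <- sim$bundle$expression
  lcpm <- cpm_normalize(em)
  tum <- em$sample_type == "01"
  expr <- lcpm[g, tum]
  names(expr) <- em$patient_id[tum]
  rec <- survival_records_quiet(sim$bundle$clinical)
  res <- survival_score(expr, rec)
  expect_equal(res$score, 1)
  expect_lt(res$p_value, 0.05)
  expect_lt(res$rmst_high, res$rmst_low)
})

test_that("non-significant or protective genes score 0", {
  set.seed(8)
  n <- 40
  expr <- setNames(seq_len(n) + rnorm(n, 0, 1e-3), sprintf("P%02d", 1:n))
  # protective: high-expression patients live much longer
  time <- ifelse(rank(expr) > n * 0.5, 2000 + seq_len(n), 50 + seq_len(n))
  rec <- data.frame(patient_id = names(expr), time = time, event = TRUE)
  res <- survival_score(expr, rec)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$score, 0)
  expect_equal(res$detail, "protective")
  # no survival signal at all
  rec2 <- data.frame(patient_id = names(expr),
                     time = sample(rep(c(100, 200, 300, 400), 10)),
                     event = TRUE)
  res2 <- survival_score(expr, rec2)
  if (res2$p_value >= 0.05) expect_equal(res2$score, 0)
})

test_that("insufficient arms yield score 0 with an insufficient detail flag", {
  expr <- setNames(c(1, 2, 3, 4), c("A", "B", "C", "D"))
  rec <- data.frame(patient_id = c("A", "B", "C", "D"),
                    time = c(10, 20, 30, 40), event = TRUE)
  res <- survival_score(expr, rec)   # below min_patients = 8
  expect_equal(res$score, 0)
  expect_equal(res$detail, "insufficient")
})
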