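test_that("EFS takes the earliest qualifying event, else censors at last assessment", {
  clin <- data.frame(sample_id = c("A", "B", "C"),
                     treatment_start = c(0, 0, 0),
                     pd_date = c(100, NA, NA),
                     treatment_change_date = c(NA, NA, 60),
                     death_date = c(NA, NA, 90),
                     last_assessment_date = c(150, 200, NA))
  efs <- build_efs(clin)
  expect_equal(efs$time, c(100, 200, 60)) # earliest event wins for C
  expect_equal(efs$event, c(1L, 0L, 1L))

  expect_error(build_efs(data.frame(sample_id = "X", treatment_start = 50,
                                    pd_date = 10, last_assessment_date = 99)),
               "event before treatment start")
  expect_error(build_efs(data.frame(sample_id = "X", treatment_start = 0,
                                    pd_date = NA, last_assessment_date = NA)),
               "neither event nor last assessment")
})

test_that("AML induction response classification follows the blast/CR rules", {
  expect_equal(classify_aml_response(post_blast_pct = 5), "responder")
  # 33% blast drop, no progression: non-responder
  expect_equal(classify_aml_response(post_blast_pct = 40, pre_blast_pct = 60),
               "non_responder")
  # 80% drop but blasts still >= 10% and no CR data: neither rule applies
  expect_equal(classify_aml_response(post_blast_pct = 12, pre_blast_pct = 60),
               "unevaluable")
  # CR with regenerated counts qualifies even at >= 10% blasts recorded
  expect_equal(classify_aml_response(post_blast_pct = 11, pre_blast_pct = 80,
                                     wbc = 2e12, platelets = 2e14,
                                     complete_response = TRUE),
               "responder")
  # insufficient regeneration blocks the CR route
  expect_equal(classify_aml_response(post_blast_pct = 11, pre_blast_pct = 80,
                                     wbc = 5e11, platelets = 2e14,
                                     complete_response = TRUE,
                                     progression = TRUE),
               "non_responder")
  expect_error(classify_aml_response(post_blast_pct = -1), "negative")
})

test_that("Kaplan-Meier estimate matches the closed-form product limit", {
  rec <- data.frame(time = 1:10, event = 1L)
  km <- km_estimate(rec)
  expect_equal(km$surv, seq(0.9, 0, by = -0.1))
  expect_equal(km$median, 5) # earliest t with S(t) <= 0.5

  # no censoring: S(t) = (# survivors > t)/n at every event time
  set.seed(51)
  t2 <- sort(sample(1:100, 12))
  km2 <- km_estimate(data.frame(time = t2, event = 1L))
  expect_equal(km2$surv, vapply(km2$time, function(tt) mean(t2 > tt), numeric(1)))

  cens <- km_estimate(data.frame(time = c(3, 6, 9), event = 0L))
  expect_true(all(cens$surv == 1))
  expect_true(is.na(cens$median))

  one <- km_estimate(data.frame(time = 7, event = 1L))
  expect_equal(one$surv, 0)
  expect_equal(one$median, 7)
})

test_that("reverse Kaplan-Meier reports median follow-up", {
  # everyone had an event: follow-up fully censored, median not reached
  expect_true(is.na(reverse_km_median_followup(data.frame(time = 1:5, event = 1L))))
  # all censored at 1, 2, 3: follow-up KM steps 2/3, 1/3 -> median 2
  expect_equal(reverse_km_median_followup(data.frame(time = 1:3, event = 0L)), 2)
  # hand-computed mixed case: censorings at 2 and 8 among events
  rec <- data.frame(time = c(1, 2, 5, 8, 9), event = c(1, 0, 1, 0, 1))
  # reverse events at 2 (S=3/4) and 8 (S=3/8) -> first S<=0.5 at time 8
  expect_equal(reverse_km_median_followup(rec), 8)
})

test_that("Cox wrapper applies and records the documented scalings", {
  set.seed(52)
  n <- 300
  auc <- runif(n, 0.2, 1)
  eln <- sample(c("favorable", "intermediate", "adverse"), n, replace = TRUE)
  h <- 0.002 * exp(1.2 * auc + 0.5 * (eln == "adverse"))
  t_ev <- rexp(n, h); cens <- runif(n, 0, 1500)
  rec <- data.frame(time = pmin(t_ev, cens), event = as.integer(t_ev <= cens),
                    auc = auc, eln = eln)

  fit <- cox_fit(rec, c(auc = "per_10pct_viability", eln = "categorical"),
                 reference = list(eln = "intermediate"))
  expect_true(fit$converged)
  # per-10% scaling: coefficient is 1/10 of the per-unit-AUC coefficient
  raw <- cox_fit(rec, c(auc = "none", eln = "categorical"),
                 reference = list(eln = "intermediate"))
  i <- match("auc", fit$terms$term)
  expect_equal(fit$terms$beta[i], raw$terms$beta[match("auc", raw$terms$term)] / 10,
               tolerance = 1e-8)
  # intermediate as reference: adverse and favorable terms reported
  expect_setequal(setdiff(fit$terms$term, "auc"),
                  c("elnadverse", "elnfavorable"))
  # CI brackets the HR and the partial likelihood improves over the null
  expect_true(all(fit$terms$lower < fit$terms$hr & fit$terms$hr < fit$terms$upper))
  expect_gte(fit$loglik, fit$loglik_null)

  # center_2sd standardization: exact reparameterization of the same model
  fit2 <- cox_fit(rec, c(auc = "center_2sd"))
  raw1 <- cox_fit(rec, c(auc = "none"))
  expect_equal(fit2$terms$beta[1], raw1$terms$beta[1] * 2 * sd(auc),
               tolerance = 1e-6)

  expect_error(cox_fit(data.frame(time = 1:5, event = 0L, x = 1:5),
                       c(x = "none")), "no events")
  expect_error(cox_fit(data.frame(time = 1:5, event = c(1, 0, 1, 0, 1), x = 1),
                       c(x = "none")), "constant")
})

test_that("symmetric groups give a hazard ratio of one", {
  rec <- data.frame(time = rep(c(1, 2, 3, 4), each = 2), event = 1L,
                    grp = rep(c(0, 1), 4))
  fit <- cox_fit(rec, c(grp = "none"))
  expect_equal(fit$terms$hr[1], 1, tolerance = 1e-8)
  expect_equal(fit$terms$p[1], 1, tolerance = 1e-8)
})

test_that("maxstat cutpoint equals exhaustive enumeration with survdiff", {
  set.seed(53)
  for (rep in 1:20) {
    n <- sample(10:15, 1)
    marker <- round(runif(n), 2)
    time <- sample(1:40, n)
    event <- rbinom(n, 1, 0.8)
    if (sum(event) == 0) event[1] <- 1L
    rec <- data.frame(time = time, event = event)
    got <- tryCatch(maxstat_cutpoint(marker, rec), error = function(e) NULL)
    if (is.null(got)) next
    want <- maxstat_oracle(marker, time, event)
    expect_equal(got$cutpoint, want$cutpoint)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
  }
})

test_that("maxstat recovers a planted survival change point", {
  set.seed(54)
  marker <- c(runif(10, 0.2, 0.45), runif(10, 0.55, 0.9))
  time <- c(rexp(10, 0.01), rexp(10, 0.15)) # high marker = much worse survival
  rec <- data.frame(time = time, event = 1L)
  cp <- maxstat_cutpoint(marker, rec)
  # the cutpoint is a marker value: the best split sits at (or within two
  # samples of) the planted boundary between the two marker groups
  expect_lt(cp$cutpoint, 0.55)
  expect_lte(abs(cp$n_responder - 10), 2)
  expect_equal(cp$n_responder + cp$n_weak_responder, 20)

  expect_error(maxstat_cutpoint(rep(0.5, 20), data.frame(time = 1:20, event = 1L)),
               "constant marker")
})
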