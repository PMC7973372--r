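test_that("Kaplan-Meier medians behave at the boundaries", {
  # everyone dies at t = 5 -> median 5
  expect_equal(km_estimate(rep(5, 10), rep(1, 10))$median, 5)
  # everyone censored -> median not reached
  expect_true(is.na(km_estimate(rep(5, 10), rep(0, 10))$median))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(1, 2), c(1, 2)), "events")
})

test_that("with no censoring the KM curve is the empirical survival function", {
  set.seed(8)
  times <- sort(stats::rexp(25, rate = 0.1))
  km <- km_estimate(times, rep(1, 25))
  s <- summary(km$fit)
  emp <- vapply(s$time, function(t) mean(times > t), numeric(1))
  expect_equal(s$surv, emp)
  # median matches the direct definition: first time S(t) <= 0.5
  expect_equal(km$median, min(s$time[s$surv <= 0.5]))
})

test_that("log-rank test is symmetric, scale-invariant, and null on ties", {
  times <- c(3, 6, 6, 9, 14, 20)
  events <- c(1, 1, 0, 1, 1, 0)
  # identical arms -> no signal
  same <- logrank(times, events, times, events)
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  # swapping arms and rescaling time never changes the statistic
  t2 <- c(2, 5, 8, 11, 12, 30)
  e2 <- c(1, 0, 1, 1, 1, 1)
  ab <- logrank(times, events, t2, e2)
  ba <- logrank(t2, e2, times, events)
  scaled <- logrank(times * 3, events, t2 * 3, e2)
  expect_equal(ab$chisq, ba$chisq)
  expect_equal(ab$p, scaled$p)
  # degenerate inputs
  expect_warning(z <- logrank(c(1, 2), c(0, 0), c(3, 4), c(0, 0)), "no events")
  expect_equal(z$p, 1)
  expect_error(logrank(numeric(0), numeric(0), 1, 1), "non-empty")
})

test_that("Mann-Whitney route matches an exhaustive permutation oracle", {
  # exact two-sided p by enumerating the null distribution of the U statistic
  mw_oracle <- function(x, y) {
    pooled <- c(x, y)
    n1 <- length(x)
    u_of <- function(idx) {
      xs <- pooled[idx]
      ys <- pooled[-idx]
      sum(outer(xs, ys, ">"))
    }
    u_obs <- sum(outer(x, y, ">"))
    us <- apply(utils::combn(length(pooled), n1), 2, u_of)
    min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  }
  set.seed(13)
  for (i in 1:10) {
    x <- round(stats::runif(4, 0, 100), 4)
    y <- round(stats::runif(5, 0, 100), 4)
    expect_equal(stats::wilcox.test(x, y)$p.value, mw_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("clinical comparisons choose the stated test per measure", {
  set.seed(4)
  n <- 80
  clinical <- data.frame(
    patient_id = sprintf("P%03d", 1:n),
    age = round(stats::rnorm(n, 65, 9)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    race = sample(c("white", "black", "asian"), n, replace = TRUE,
                  prob = c(0.8, 0.12, 0.08)),
    stage = sample(c("resectable", "borderline", "locally advanced",
                     "metastatic"), n, replace = TRUE),
    surgery = sample(c(TRUE, FALSE), n, replace = TRUE),
    ca19_9_producer = sample(c(TRUE, FALSE), n, replace = TRUE,
                             prob = c(0.7, 0.3)),
    ca19_9 = stats::rlnorm(n, 5, 1.5),
    os_months = stats::rexp(n, log(2) / 12),
    vital_status = stats::rbinom(n, 1, 0.8),
    stringsAsFactors = FALSE
  )
  membership <- stats::setNames(seq_len(n) <= 25, clinical$patient_id)

  age_row <- compare_clinical(membership, clinical, "age")
  expect_equal(age_row$test, "mann_whitney")
  expect_equal(age_row$p,
               stats::wilcox.test(clinical$age[membership],
                                  clinical$age[!membership])$p.value)
  expect_equal(as.numeric(age_row$group_value),
               stats::median(clinical$age[membership]))

  # CA19-9 restricted to producers
  ca_row <- compare_clinical(membership, clinical, "ca19_9")
  prod <- clinical$ca19_9_producer
  expect_equal(ca_row$n_group + ca_row$n_rest, sum(prod))
  expect_equal(ca_row$p,
               stats::wilcox.test(clinical$ca19_9[membership & prod],
                                  clinical$ca19_9[!membership & prod])$p.value)

  # binary sex table at this size: expected counts >= 5 -> chi-square
  sex_row <- compare_clinical(membership, clinical, "sex")
  expect_equal(sex_row$test, "chi_square")
  expect_equal(sex_row$p,
               suppressWarnings(stats::chisq.test(
                 table(membership, clinical$sex))$p.value))

  # sparse categories switch to Fisher's exact test
  clin_small <- clinical[1:12, ]
  clin_small$race <- rep(c("white", "black"), 6)
  memb_small <- stats::setNames(rep(c(TRUE, FALSE), 6),
                                clin_small$patient_id)
  race_row <- compare_clinical(memb_small, clin_small, "race")
  expect_equal(race_row$test, "fisher_exact")
  expect_equal(race_row$p,
               stats::fisher.test(table(memb_small, clin_small$race))$p.value)

  # survival route reports KM medians and the log-rank p
  os_row <- compare_clinical(membership, clinical, "os")
  expect_equal(os_row$test, "logrank")
  lr <- logrank(clinical$os_months[membership],
                clinical$vital_status[membership],
                clinical$os_months[!membership],
                clinical$vital_status[!membership])
  expect_equal(os_row$p, lr$p)

  # subgroup filters restrict the rows entering the test
  met_row <- compare_clinical(membership, clinical, "age",
                              filter = "metastatic")
  expect_equal(met_row$n_group + met_row$n_rest,
               sum(clinical$stage == "metastatic"))

  # degenerate split returns NULL instead of a spurious p-value
  expect_null(compare_clinical(stats::setNames(rep(TRUE, n),
                                               clinical$patient_id),
                               clinical, "age"))
})

test_that("the full comparison grid reports raw and BH-adjusted p-values", {
  st <- run_small_study(17)
  qual <- variant_group_matrix(st$calls, st$flags, st$enrichment,
                               load_group_predicates(), load_gene_sets())
  memb <- assign_groups(qual, st$dosage)$membership
  out <- run_table4(memb, st$clinical, alpha = 0.05)
  expect_true(all(c("group", "measure", "filter", "p", "p_bh") %in%
                    names(out$full)))
  expect_equal(out$full$p_bh, stats::p.adjust(out$full$p, method = "BH"))
  expect_true(all(out$significant$p < 0.05))
  expect_true(nrow(out$significant) <= nrow(out$full))
  # every reported group id comes from the predicate configuration
  expect_true(all(out$full$group %in% colnames(memb)))
})
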