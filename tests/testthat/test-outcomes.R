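test_that("cohort summary counts, percentages and formatting", {
  cl <- data.frame(sample_id = as.character(1:10), response = "R",
                   os_days = 100, event = 0, sex = "M",
                   stringsAsFactors = FALSE)
  cl$response[1:5] <- "NR"
  s <- cohort_summary(cl)
  male <- s[s$covariate == "sex" & s$group == "R", ]
  expect_equal(male$n, 5)
  expect_equal(male$label, "5 (100%)")
  # one decimal below 10 percent
  cl2 <- table1_clinical()
  s2 <- cohort_summary(cl2)
  dead_r <- s2[s2$covariate == "status" & s2$level == "Deceased" &
               s2$group == "R", ]
  expect_equal(dead_r$label, "1 (7.1%)")
  expect_error(cohort_summary(data.frame(sample_id = "a")), "response")
})

test_that("response tests flag constants and skip mostly-missing features", {
  groups <- data.frame(sample_id = paste0("s", 1:8),
                       response = rep(c("R", "NR"), each = 4))
  fm <- data.frame(sample_id = paste0("s", 1:8),
                   const = 1,
                   mostly_na = c(1, NA, NA, NA, NA, NA, NA, 2),
                   ok = rnorm(8))
  res <- feature_response_tests(fm, groups)
  expect_equal(attr(res, "skipped"), "mostly_na")
  cons <- res[res$feature == "const", ]
  expect_equal(cons$p, 1)
  expect_equal(cons$flag, "zero_variance")
})

test_that("logistic AUC hits its extremes and nested-model property", {
  cl <- data.frame(sample_id = paste0("s", 1:20),
                   response = rep(c("NR", "R"), each = 10),
                   stringsAsFactors = FALSE)
  set.seed(1)
  fm <- data.frame(sample_id = paste0("s", 1:20),
                   perfect = c(rnorm(10, 0), rnorm(10, 100)),
                   weak = rnorm(20))
  res <- logistic_auc(fm, cl)
  expect_equal(res$auc[res$model == "perfect"], 1)
  expect_true(res$separation[res$model == "perfect"])
  mv <- res$auc[res$model == "multivariate"]
  expect_gte(mv, max(res$auc[res$model != "multivariate"]) - 1e-9)
  expect_error(logistic_auc(fm, transform(cl, response = "R")), "2 samples")
})

test_that("an uninformative feature scores AUC about one half", {
  set.seed(2)
  n <- 200
  cl <- data.frame(sample_id = paste0("s", 1:n),
                   response = sample(rep(c("R", "NR"), each = n / 2)),
                   stringsAsFactors = FALSE)
  fm <- data.frame(sample_id = paste0("s", 1:n), f = rnorm(n))
  res <- logistic_auc(fm, cl)
  expect_lt(abs(res$auc[res$model == "f"] - 0.5), 0.1)
})

test_that("Cox estimates are per-SD and invariant to sample duplication", {
  set.seed(3)
  n <- 120
  f <- rnorm(n)
  cl <- data.frame(sample_id = paste0("s", 1:n),
                   os_days = rexp(n, rate = exp(0.7 * f) / 500),
                   event = 1L, stringsAsFactors = FALSE)
  fit1 <- cox_continuous(f, cl)
  expect_gt(fit1$hr, 1)
  expect_true(fit1$ci[1] < fit1$hr && fit1$hr < fit1$ci[2])
  dup <- rbind(cl, transform(cl, sample_id = paste0(sample_id, "b")))
  fit2 <- cox_continuous(c(f, f), dup)
  # exact invariance holds under Breslow ties; the Efron correction (the
  # deliberate default) perturbs duplicated event times at O(1/n)
  expect_equal(fit2$hr, fit1$hr, tolerance = 0.01)
  expect_error(cox_continuous(f, transform(cl, event = 0L)), "no events")
})

test_that("median-cut KM honours ties-to-low, null and degenerate contracts", {
  n <- 20
  cl <- data.frame(sample_id = paste0("s", 1:n),
                   os_days = rep(seq(100, 1000, by = 100), 2),
                   event = 1L, stringsAsFactors = FALSE)
  # identical survival patterns on both sides of the split
  f <- rep(c(0, 1), each = 10)
  km <- km_median_split(f, cl)
  expect_gt(km$logrank_p, 0.99)
  expect_equal(unname(table(km$group)["low"]), 10)  # ties (<= median) go low
  # KM starts at 1
  expect_true(all(summary(km$km, times = 0)$surv == 1))
  expect_error(km_median_split(rep(1, n), cl), "degenerate")
})

test_that("the survival screen collects Cox and log-rank results per feature", {
  set.seed(4)
  n <- 60
  cl <- data.frame(sample_id = paste0("s", 1:n),
                   response = rep(c("R", "NR"), each = n / 2),
                   os_days = rexp(n, 1 / 500), event = rbinom(n, 1, 0.8),
                   stringsAsFactors = FALSE)
  fm <- data.frame(sample_id = paste0("s", 1:n), f1 = rnorm(n), f2 = rnorm(n))
  res <- survival_screen(fm, cl)
  expect_equal(res$feature, c("f1", "f2"))
  expect_true(all(res$hr > 0))
  expect_true(all(res$ci_low <= res$hr & res$hr <= res$ci_high))
})
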