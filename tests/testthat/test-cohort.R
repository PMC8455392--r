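test_that("the OARSI grade partition is total and exact on 0..4", {
  expect_equal(assign_group(0:4),
               c("normal", "normal", "moderate", "moderate", "severe"))
  expect_error(assign_group(5), "0..4")
  expect_error(assign_group(-1), "0..4")
  expect_error(assign_group(2.5), "0..4")
})

test_that("descriptive summaries handle degenerate groups", {
  d <- data.frame(group = c("normal", "normal", "severe"),
                  knee_id = c("K1", "K2", "K3"),
                  Enf = c(0.7, 0.9, 0.3))
  s <- summarize_cohort(d, "Enf", B = 50)
  sv <- s$summary[s$summary$group == "severe", ]
  expect_equal(sv$mean, 0.3)
  expect_true(is.na(sv$sd))       # single sample: SD undefined, flagged NA
  expect_null(s$contrasts)        # groups below min_n_test: no contrast
})

test_that("identical groups give a zero mean difference with a covering CI", {
  x <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  d <- data.frame(group = rep(c("normal", "moderate"), each = 5),
                  knee_id = paste0("K", 1:10),
                  Enf = c(x, x))
  s <- summarize_cohort(d, "Enf", B = 500, seed = 2, min_n_test = 5)
  expect_equal(s$contrasts$estimate, 0)
  expect_lte(s$contrasts$ci_lower, 0)
  expect_gte(s$contrasts$ci_upper, 0)
})

test_that("a configured group effect is recovered across replicates", {
  # known effect on Enf: moderate median raised by 30% over normal
  med_n <- c(Ef0 = 0.9, EfEps = 40, Enf = 0.7, k0 = 2, M = 10)
  med_m <- med_n; med_m["Enf"] <- med_n["Enf"] * 1.3
  sg <- c(Ef0 = 0.35, EfEps = 0.35, Enf = 0.3, k0 = 0.35, M = 0.3)
  model <- group_parameter_model(
    medians = list(normal = med_n, moderate = med_m, severe = med_n),
    sigmas = list(normal = sg, moderate = sg, severe = sg))
  delta_true <- 0.7 * (1.3 - 1) * exp(0.3^2 / 2)  # log-normal mean difference
  est <- vapply(1:200, function(r) {
    coh <- generate_cohort(cohort_spec(model = model), seed = 7000 + r)
    d <- coh$samples
    mean(d$Enf[d$group == "moderate"]) - mean(d$Enf[d$group == "normal"])
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - delta_true), 4 * mc_se + 0.005)
})

test_that("bootstrap contrasts are reproducible under a fixed seed", {
  coh <- generate_cohort(cohort_spec(), seed = 4)
  s1 <- summarize_cohort(coh$samples, c("Enf", "k0"), B = 300, seed = 11)
  s2 <- summarize_cohort(coh$samples, c("Enf", "k0"), B = 300, seed = 11)
  expect_identical(s1$contrasts, s2$contrasts)
  # severe group (n = 3) is summarized but excluded from testing
  expect_true("severe" %in% s1$summary$group)
  expect_match(attr(s1$contrasts, "note"), "severe")
})

test_that("compartment stratification partitions the cohort", {
  coh <- generate_cohort(cohort_spec(), seed = 4)
  s <- summarize_cohort(coh$samples, "Enf", by_compartment = TRUE, B = 50)
  expect_equal(sum(s$summary$n), nrow(coh$samples))
})
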