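# Mixed models, effect sizes, subtraction predictor, corrections.

test_that("LMM recovers a noise-free linear stage effect exactly", {
  # zero residual variance: only the point estimate is meaningful here
  tab <- linear_stage_table(6, 10, slope = 0.01, noise_sd = 0)
  m <- quiet_fit(fit_stage_lmm(tab, "MI"))
  est <- m$terms$estimate[m$terms$term == "stage_code"]
  expect_equal(round(est, 4), 0.01)
  expect_length(m$residual_quantiles, 99)
})

test_that("LMM stage term is detected on noisy cohorts and respects the SWS restriction", {
  tab <- linear_stage_table(8, 12, slope = 0.01, noise_sd = 0.03, seed = 21)
  m <- quiet_fit(fit_stage_lmm(tab, "MI"))
  r <- m$terms[m$terms$term == "stage_code", ]
  expect_gt(r$estimate, 0)
  expect_lt(r$p_corrected, 0.05)
  # SWS control requires two-stage patients carrying SWS rows
  sws <- tab[tab$stage == "Iso", ]
  sws$stage <- "SWS"
  tab2 <- rbind(tab[tab$stage != "Iso", ], sws)
  tab2$surgery_stages <- 2L
  m2 <- quiet_fit(fit_stage_lmm(tab2, "MI", control = "SWS"))
  expect_gt(m2$terms$estimate[m2$terms$term == "stage_code"], 0)
  expect_error(fit_stage_lmm(tab[tab$patient_id == "P01", ], "MI"),
               "two patients")
})

test_that("GLMM is null-calibrated and recovers a known logistic slope", {
  set.seed(31)
  # null: labels independent of the biomarker
  tab <- linear_stage_table(8, 16, slope = 0, noise_sd = 0.05, seed = 31)
  tab <- tab[tab$stage == "Sev3", ]
  tab$is_resected <- rep(c(TRUE, FALSE), length.out = nrow(tab))
  m0 <- quiet_fit(fit_epi_glmm(tab, "MI", "Sev3"))
  r0 <- m0$terms[m0$terms$term == "value", ]
  expect_equal(r0$or, 1, tolerance = 0.75)
  expect_gt(r0$p_corrected, 0.5)

  # recovery: log-odds = -1 + 2 * value over ~1500 channels
  ests <- sapply(1:5, function(seed) {
    set.seed(seed)
    n_pat <- 12; n_ch <- 125
    val <- rnorm(n_pat * n_ch, 0, 1)
    d <- data.frame(
      patient_id = rep(sprintf("P%02d", 1:n_pat), each = n_ch),
      channel = sprintf("C%04d", seq_along(val)), stage = "Sev3",
      epoch_index = 1L, biomarker = "MI", value = val, normative = FALSE,
      is_resected = rbinom(length(val), 1, plogis(-1 + 2 * val)) == 1,
      is_soz = FALSE, is_lesional = FALSE, has_ied = FALSE,
      age_years = 10, sex = "M", hemisphere = "L", n_asm = 1L,
      daily_seizures = FALSE, surgery_stages = 1L)
    m <- quiet_fit(fit_epi_glmm(d, "MI", "Sev3"))
    m$terms$estimate[m$terms$term == "value"]
  })
  expect_lt(abs(mean(ests) - 2) / 2, 0.15)
})

test_that("Cohen's d matches the direct arithmetic definition and its invariances", {
  mk <- function(vals, resected) {
    d <- make_channels(length(vals))
    data.frame(patient_id = "P01", channel = d$label, stage = "Sev4",
               epoch_index = 1L, biomarker = "MI", value = vals,
               normative = !resected, is_resected = resected,
               is_soz = FALSE, is_lesional = FALSE, has_ied = FALSE,
               age_years = 10, sex = "M", hemisphere = "L", n_asm = 0L,
               daily_seizures = FALSE, surgery_stages = 1L)
  }
  tab <- mk(c(2, 2, 1, 1, 1), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  d <- cohens_d_by_stage(tab, "MI")
  expect_equal(d$d, 1 / sd(c(2, 2, 1, 1, 1)), tolerance = 1e-12)
  expect_equal(d$d, 1.8257, tolerance = 1e-4)
  # equal class means give zero; common rescaling leaves d unchanged
  t0 <- mk(c(1, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cohens_d_by_stage(t0, "MI")$d, 0)
  tab2 <- tab; tab2$value <- tab$value * 2
  expect_equal(cohens_d_by_stage(tab2, "MI")$d, d$d)
  # a patient-epoch with a single class is skipped
  one <- mk(c(1, 2), c(TRUE, TRUE))
  expect_error(cohens_d_by_stage(one, "MI"), "both classes")
})

test_that("subtraction predictor averages resected minus retained per patient", {
  mk <- function(vals, resected, pid) {
    data.frame(patient_id = pid, channel = paste0(pid, "_", seq_along(vals)),
               stage = "Sev4", epoch_index = 1L, biomarker = "MI",
               value = vals, normative = !resected, is_resected = resected,
               is_soz = FALSE, is_lesional = FALSE, has_ied = FALSE,
               age_years = 10, sex = "M", hemisphere = "L", n_asm = 0L,
               daily_seizures = FALSE, surgery_stages = 1L)
  }
  tab <- rbind(mk(c(3, 1, 1, 1), c(TRUE, TRUE, FALSE, FALSE), "P01"),
               mk(c(1, 1, 1, 1), c(TRUE, TRUE, FALSE, FALSE), "P02"),
               mk(c(5, 5, 5, 5), rep(TRUE, 4), "P03"))
  expect_warning(s <- subtraction_predictor(tab, "MI", "Sev4"), "P03")
  expect_equal(s$subtraction[s$patient_id == "P01"], 1)
  expect_equal(s$subtraction[s$patient_id == "P02"], 0)
  expect_false("P03" %in% s$patient_id)
  out <- c(P01 = TRUE, P02 = FALSE)
  expect_warning(s2 <- subtraction_predictor(tab, "MI", "Sev4",
                                             outcome = out), "P03")
  expect_s3_class(attr(s2, "outcome_model"), "glm")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.001, 40), 0.04)
  expect_equal(bonferroni_adjust(0.5, 6), 1)
  expect_equal(bonferroni_adjust(0, 1000), 0)
  expect_error(bonferroni_adjust(1.2, 2))
})

test_that("log transform is rank-preserving and applies the offset only with zeros", {
  tab <- linear_stage_table(3, 5, slope = 0.01, noise_sd = 0.01, seed = 41)
  tab$value <- abs(tab$value) + 0.01
  lt <- log_variant(tab)
  expect_equal(order(lt$value), order(tab$value))
  expect_equal(lt$value, log(tab$value))        # no zeros: eps = 0
  tab0 <- tab; tab0$value[1] <- 0
  lt0 <- log_variant(tab0)
  eps <- min(tab0$value[tab0$value > 0]) / 2
  expect_equal(lt0$value[1], log(eps))
  taz <- tab; taz$value <- 0
  expect_error(log_variant(taz), "identically zero")
  # a strong positive stage effect keeps its sign after the transform
  m <- quiet_fit(fit_stage_lmm(log_variant(tab), "MI"))
  expect_gt(m$terms$estimate[m$terms$term == "stage_code"], 0)
})
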