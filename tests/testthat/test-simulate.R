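# Synthetic cohort generator: determinism, encoded effects, artifacts, truth.

test_that("generation is bit-identical for a fixed seed and annotated per schedule", {
  cfg <- sim_config(n_patients = 1, n_channels = 2, fs = 1000,
                    stage_schedule = c(Iso = 30, Sev2 = 30),
                    sws_duration_s = 0, frac_two_stage = 0, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$recordings[[1]]$samples, b$recordings[[1]]$samples)
  expect_identical(a$truth$edges, b$truth$edges)
  rec <- a$recordings[[1]]
  expect_equal(rec$annotations$stage, c("Iso", "Sev2"))
  expect_equal(ncol(rec$samples), 60 * 1000)
  expect_error(sim_config(stage_schedule = c(Iso = 0)), "degenerate")
})

test_that("config validation rejects tables breaking ranges or the dissociation", {
  tweak <- sim_config()
  bad_kappa <- tweak$kappa
  bad_kappa["Sev3", "epileptogenic"] <- 0.1     # below normative: breaks dissociation
  expect_error(sim_config(kappa = bad_kappa), "dissociation")
  neg <- tweak$kappa; neg["Iso", 1] <- -0.2
  expect_error(sim_config(kappa = neg), "\\[0, 1\\]")
})

test_that("measured MI rises monotonically with injected coupling depth", {
  kappas <- c(0, 0.2, 0.4, 0.8)
  mi_mean <- sapply(kappas, function(kap) {
    tab <- .stage_class_table(c(kap, kap), c(kap, kap), c(kap, kap),
                              c(kap, kap), c(kap, kap))
    mean(sapply(1:10, function(seed) {
      cfg <- sim_config(n_patients = 1, n_channels = 1, fs = 1000,
                        stage_schedule = c(Iso = 40), sws_duration_s = 0,
                        frac_two_stage = 0, frac_epileptogenic = 0,
                        kappa = tab, seed = seed)
      rec <- generate_cohort(cfg)$recordings[[1]]
      modulation_index(rec$samples[1, ], 1000)$mi
    }))
  })
  expect_true(all(diff(mi_mean) > 0))
  # kappa = 0 channels show no coupling beyond the sparse-burst sampling
  # floor: the surrogate test stays null
  tab0 <- .stage_class_table(c(0, 0), c(0, 0), c(0, 0), c(0, 0), c(0, 0))
  cfg0 <- sim_config(n_patients = 1, n_channels = 1, fs = 1000,
                     stage_schedule = c(Iso = 40), sws_duration_s = 0,
                     frac_two_stage = 0, frac_epileptogenic = 0,
                     kappa = tab0, seed = 3)
  rec0 <- generate_cohort(cfg0)$recordings[[1]]
  expect_lt(surrogate_mi_z(rec0$samples[1, ], 1000, n_surrogates = 100,
                           seed = 1), 2)
})

test_that("a planted directed edge dominates the reverse direction", {
  wins <- 0L
  for (seed in 1:10) {
    cfg <- sim_config(n_patients = 1, n_channels = 2, fs = 1000,
                      stage_schedule = c(Iso = 60, Sev4 = 120),
                      sws_duration_s = 0, frac_two_stage = 0,
                      frac_epileptogenic = 0, edge_density = 0.5,
                      p_propagate_hfo = .stage_class_table(
                        c(0.9, 0.9), c(0.9, 0.9), c(0.9, 0.9),
                        c(0.9, 0.9), c(0.9, 0.9)),
                      seed = seed)
    gen <- generate_cohort(cfg)
    ed <- gen$truth$edges
    if (is.null(ed) || nrow(ed) != 1L) next
    rec <- preprocess_recording(gen$recordings[[1]])
    segs <- segment_stages(rec)
    zh <- zscore_to_control(wavelet_amplitude(rec, "hfo"), segs, "Iso")
    sev <- segs[segs$stage == "Sev4", ]
    bb <- binarize_bursts(zh, sev$start_sample[1],
                          sev$end_sample[nrow(sev)])
    i <- match(ed$src, gen$recordings[[1]]$channels$label)
    j <- match(ed$dst, gen$recordings[[1]]$channels$label)
    fwd <- as.numeric(transfer_entropy(bb$bits[i, ], bb$bits[j, ]))
    rev <- as.numeric(transfer_entropy(bb$bits[j, ], bb$bits[i, ]))
    if (fwd > rev) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("artifact injection obeys the rate, marks its mask, and is inert at rate 0", {
  cfg <- sim_config(n_patients = 1, n_channels = 1, fs = 1000,
                    stage_schedule = c(Iso = 600), sws_duration_s = 0,
                    frac_two_stage = 0, seed = 5)
  rec <- generate_cohort(cfg)$recordings[[1]]
  nul <- inject_artifacts(rec, rate = 0)
  expect_identical(nul$rec$samples, rec$samples)
  expect_false(any(nul$mask$bad))
  inj <- inject_artifacts(rec, rate = 2, seed = 17)
  rngs <- mask_ranges(inj$mask)[[1]]
  n_events <- nrow(rngs)
  expect_true(abs(n_events - 20) <= 3 * sqrt(20))   # Poisson(20) within 3 sd
  # corrupted samples lie inside the mask
  changed <- which(inj$rec$samples[1, ] != rec$samples[1, ])
  expect_true(all(inj$mask$bad[1, changed]))
})

test_that("ground truth round-trips through JSON and refuses non-finite kappa", {
  cfg <- sim_config(n_patients = 2, n_channels = 3, fs = 1000,
                    stage_schedule = c(Iso = 5), sws_duration_s = 0,
                    frac_two_stage = 0, seed = 2)
  truth <- generate_cohort(cfg)$truth
  f <- withr::local_tempfile(fileext = ".json")
  export_truth(truth, f)
  back <- load_truth(f)
  expect_equal(back$kappa, truth$kappa)
  expect_equal(back$classes, truth$classes)
  expect_equal(back$edges$src, truth$edges$src)
  expect_equal(back$seed, truth$seed)
  truth$kappa[1, 1] <- NaN
  expect_error(export_truth(truth, f), "non-finite")
})
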