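# Recording container, EDF round trip, montage derivation, stage epochs.

test_that("EDF round trip preserves samples within quantization and metadata exactly", {
  set.seed(1)
  x <- matrix(rnorm(4 * 5000, sd = 80), 4)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(x, 1000, c("G1", "G2", "G3", "G4"), f)
  e <- read_edf(f)
  step <- max(abs(x)) / 32767
  expect_lt(max(abs(e$samples - x)), 2 * step)
  expect_identical(e$labels, c("G1", "G2", "G3", "G4"))
  expect_equal(e$fs, 1000)
})

test_that("load_recording joins sidecars and rejects inconsistent inputs", {
  set.seed(2)
  dir <- withr::local_tempdir()
  ch <- make_channels(4, labels = c("G11", "G12", "G13", "G14"))
  ann <- data.frame(stage = c("Iso", "Sev2"), start_sample = c(0L, 3000L),
                    end_sample = c(3000L, 6000L))
  rec <- recording(matrix(rnorm(4 * 6000, sd = 50), 4), 1000, ch, ann)
  paths <- write_recording(rec, dir)

  back <- load_recording(paths$signal, paths$meta, paths$annot)
  expect_equal(nrow(back$samples), 4)
  expect_equal(back$fs, 1000)
  expect_identical(back$channels$label, ch$label)
  expect_identical(back$annotations$stage, ann$stage)
  expect_equal(back$annotations$start_sample, ann$start_sample)

  # sidecar missing a channel names it
  meta2 <- utils::read.csv(paths$meta)
  utils::write.csv(meta2[meta2$label != "G12", ], paths$meta,
                   row.names = FALSE)
  expect_error(load_recording(paths$signal, paths$meta, paths$annot), "G12")

  # annotation beyond the file is rejected
  utils::write.csv(meta2, paths$meta, row.names = FALSE)
  bad_ann <- file.path(dir, "bad.json")
  jsonlite::write_json(data.frame(stage = "Iso", start_s = 0, end_s = 99),
                       bad_ann, digits = NA)
  expect_error(load_recording(paths$signal, paths$meta, bad_ann),
               "outside")
  # sampling-rate mismatch is a hard error
  expect_error(load_recording(paths$signal, paths$meta, paths$annot,
                              fs_expected = 512), "mismatch")
})

test_that("bipolar derivation subtracts pairs, ORs flags, and is linear", {
  fs <- 1000
  t <- seq_len(2000) / fs
  s <- sin(2 * pi * 7 * t)
  ch <- make_channels(3, labels = c("A1", "A2", "A3"))
  ch$is_resected[2] <- TRUE
  samples <- rbind(s, s, 0 * s)
  ann <- data.frame(stage = "Iso", start_sample = 0L, end_sample = 2000L)
  rec <- recording(samples, fs, ch, ann)
  pairs <- data.frame(anode = c("A1", "A1", "A2"),
                      cathode = c("A1", "A3", "A3"))
  bp <- to_bipolar(rec, pairs)
  expect_equal(bp$samples[1, ], rep(0, 2000))        # anode == cathode
  expect_equal(bp$samples[2, ], s)                   # minus zero reference
  expect_identical(bp$montage, "bipolar")
  expect_false(bp$channels$is_resected[2])
  expect_true(bp$channels$is_resected[3])            # flag OR with resected A2
  expect_match(bp$channels$label[2], "A1-A3")
  expect_error(to_bipolar(rec, data.frame(anode = "A1", cathode = "ZZ")),
               "ZZ")
  # linearity: scaling the recording scales the derivation
  rec2 <- rec; rec2$samples <- 3 * rec$samples
  bp2 <- to_bipolar(rec2, pairs)
  expect_equal(bp2$samples, 3 * bp$samples)
})

test_that("stage segmentation yields 1-min epochs and marks analysis epochs", {
  fs <- 200  # small fs keeps the fixture light
  mk <- function(stages_s) {
    ends <- cumsum(stages_s) * fs
    data.frame(stage = names(stages_s),
               start_sample = as.integer(c(0, ends[-length(ends)])),
               end_sample = as.integer(ends))
  }
  ann <- mk(c(Iso = 300, Sev2 = 300, Sev3 = 300, Sev4 = 300))
  n <- 1200 * fs
  rec <- recording(matrix(0, 1, n) + rnorm(n), fs, make_channels(1), ann)
  seg <- segment_stages(rec)
  expect_equal(nrow(seg), 20)                        # 20 one-minute epochs
  expect_equal(sum(seg$is_analysis & seg$stage != "Iso"), 9)
  expect_false(any(duplicated(unlist(Map(seq, seg$start_sample,
                                         seg$end_sample - 1L)))))
  # a masked epoch is excluded from analysis epochs and later ones promoted
  bad <- matrix(FALSE, 1, n)
  bad[1, (seg$start_sample[6] + 1):seg$end_sample[6]] <- TRUE  # Sev2 epoch 1
  rec2 <- set_mask(rec, artifact_mask(bad))
  seg2 <- segment_stages(rec2)
  sev2 <- seg2[seg2$stage == "Sev2", ]
  expect_false(sev2$is_analysis[1])
  expect_equal(sev2$epoch_index[sev2$is_analysis], 2:4)
  # SWS-only recording: control epochs only, no sevoflurane epochs
  annS <- mk(c(SWS = 300))
  recS <- recording(matrix(rnorm(300 * fs), 1), fs, make_channels(1), annS)
  segS <- segment_stages(recS)
  expect_equal(nrow(segS), 5)
  expect_true(all(segS$stage == "SWS"))
})

test_that("recording validation rejects overlap, unknown stages and bad ranges", {
  ch <- make_channels(1)
  x <- matrix(0, 1, 100)
  expect_error(recording(x, 1000, ch, data.frame(
    stage = "Nap", start_sample = 0L, end_sample = 50L)), "unknown stage")
  expect_error(recording(x, 1000, ch, data.frame(
    stage = c("Iso", "Sev2"), start_sample = c(0L, 40L),
    end_sample = c(50L, 90L))), "overlap")
  expect_error(recording(x, 1000, ch, data.frame(
    stage = "Iso", start_sample = 0L, end_sample = 200L)), "outside")
})
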