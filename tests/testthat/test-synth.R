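test_that("generated beats have the configured geometry", {
  morph_neg <- beat_morphology(j_amplitude = 0)
  beat <- generate_beat(morph_neg, fs = 500, rr = 1.0)
  expect_length(beat, 500)
  # R is the largest configured amplitude, so the global max is at its centre
  expect_equal(which.max(beat), attr(beat, "r_index"))
  # returns to baseline at the beat end
  expect_lt(abs(beat[length(beat)]), 0.05)

  morph_pos <- beat_morphology(j_amplitude = 0.15)
  pos <- generate_beat(morph_pos, fs = 500, rr = 1.0)
  diffs <- pos - beat
  r <- attr(beat, "r_index")
  j_center <- r + round(morph_pos$j_offset * 500)
  # additive bump: max |difference| ~ j_amplitude at j_offset
  expect_equal(which.max(abs(diffs)), j_center)
  expect_equal(max(abs(diffs)), morph_pos$j_amplitude, tolerance = 1e-6)
  # difference identical to zero outside j_offset +/- 3 widths
  far <- abs(seq_along(beat) - j_center) > 3 * morph_pos$j_width * 500
  expect_lt(max(abs(diffs[far])), 0.05 * morph_pos$j_amplitude)
})

test_that("positive-vs-negative template difference is confined to the post-R window", {
  neg <- generate_beat(beat_morphology(), fs = 500, rr = 1.0)
  pos <- generate_beat(beat_morphology(j_amplitude = 0.15), fs = 500, rr = 1.0)
  d2 <- (pos - neg)^2
  r <- attr(neg, "r_index")
  inside <- sum(d2[(r + 1):(r + 120)])
  expect_gt(inside / sum(d2), 0.99)
})

test_that("generate_beat validates physiology", {
  expect_error(generate_beat(beat_morphology(), rr = 0.2), "rr")
  expect_error(generate_beat(beat_morphology(), rr = 3), "rr")
  expect_error(generate_beat(beat_morphology(), fs = -1), "fs")
  expect_error(beat_morphology(j_amplitude = 0.1, j_offset = 0.3),
               "post-R window")
})

test_that("records concatenate beats with exact R bookkeeping", {
  rec <- generate_record(20, beat_morphology(), noise_none(), fs = 500,
                         mean_hr = 60, hr_jitter = 0, seed = 4)
  expect_s3_class(rec, "ecg_record")
  expect_length(rec$true_r_indices, 20)
  # zero jitter: R indices exactly periodic with period fs * 60 / hr
  expect_equal(unique(diff(rec$true_r_indices)), 500L)
  expect_equal(length(rec$samples), 20 * 500)

  # determinism: same seed gives bit-identical samples
  rec2 <- generate_record(20, beat_morphology(), noise_none(), fs = 500,
                          mean_hr = 60, hr_jitter = 0, seed = 4)
  expect_identical(rec$samples, rec2$samples)
  noisy1 <- generate_record(10, beat_morphology(), noise_spec(), seed = 9)
  noisy2 <- generate_record(10, beat_morphology(), noise_spec(), seed = 9)
  expect_identical(noisy1$samples, noisy2$samples)
  expect_false(identical(
    noisy1$samples,
    generate_record(10, beat_morphology(), noise_spec(), seed = 10)$samples))
})

test_that("long records have the advertised scale", {
  rec <- generate_record(1200, beat_morphology(), noise_none(), fs = 500,
                         mean_hr = 60, hr_jitter = 0.05, seed = 2)
  expect_length(rec$true_r_indices, 1200)
  expect_equal(length(rec$samples), 600000, tolerance = 0.05)
  expect_true(all(diff(rec$true_r_indices) > 0))
})

test_that("dataset split is by record and labels are sound", {
  ds <- generate_dataset(n_negative = 30, n_positive = 25,
                         beats_per_record = 2, seed = 1)
  m <- ds$manifest
  expect_equal(sum(m$label == "negative"), 30)
  expect_equal(sum(m$label == "positive"), 25)
  # 60% record-level split mirrors an 18/12 and 15/10 partition
  expect_equal(sum(m$split == "train" & m$label == "negative"), 18)
  expect_equal(sum(m$split == "train" & m$label == "positive"), 15)
  expect_equal(sum(m$split == "test" & m$label == "negative"), 12)
  expect_equal(sum(m$split == "test" & m$label == "positive"), 10)
  expect_length(intersect(m$record_id[m$split == "train"],
                          m$record_id[m$split == "test"]), 0)
  for (rec in ds$records) {
    expect_equal(rec$label, m$label[m$record_id == rec$record_id])
  }

  ds2 <- generate_dataset(n_negative = 2, n_positive = 2,
                          beats_per_record = 2, seed = 1, train_frac = 0.6)
  expect_equal(as.vector(table(ds2$manifest$split)), c(2, 2))
  expect_error(generate_dataset(n_negative = 1, n_positive = 1,
                                beats_per_record = 2, seed = 1),
               "infeasible")
})

test_that("dataset generation is deterministic and separation-aware", {
  d1 <- generate_dataset(2, 2, beats_per_record = 3, seed = 7)
  d2 <- generate_dataset(2, 2, beats_per_record = 3, seed = 7)
  expect_identical(lapply(d1$records, `[[`, "samples"),
                   lapply(d2$records, `[[`, "samples"))
  # separation = 0: positive records carry no J bump but keep their label
  d0 <- generate_dataset(2, 2, beats_per_record = 3, seed = 7, separation = 0)
  expect_equal(d0$manifest$label, c("negative", "negative",
                                    "positive", "positive"))
})

test_that("records round-trip through CSV and the manifest through JSON", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(2, 2, beats_per_record = 3, seed = 3)
  write_dataset(ds, dir)
  rec <- ds$records[[1]]
  back <- read_record(dir, rec$record_id)
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$label, rec$label)
  expect_equal(back$true_r_indices, rec$true_r_indices)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$record_id, ds$manifest$record_id)
  expect_equal(man$split, ds$manifest$split)
})
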