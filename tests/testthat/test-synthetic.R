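test_that("background epochs are deterministic, shaped and band-limited", {
  cfg <- generator_config()
  a <- gen_background(cfg, seed = 5)
  b <- gen_background(cfg, seed = 5)
  expect_identical(a$data, b$data)
  expect_equal(dim(a$data), c(19, 1024))
  expect_identical(a$channel_names, channels_1020)
  expect_equal(a$label, "normal")
  # physiological amplitude: tens of microvolts RMS
  rms <- sqrt(rowMeans(a$data^2))
  expect_true(all(rms > 10 & rms < 80))
  # spectral mass concentrated below 25 Hz
  for (ch in c(1, 10)) {
    p <- compute_psd(a$data[ch, ], cfg$fs)
    expect_gt(band_energy(p, 0, 25) / band_energy(p, 0, 70), 0.8)
  }
})

test_that("discharge templates respect their clinical bounds", {
  cfg <- generator_config()
  set.seed(1)
  for (k in 1:1000) {
    w <- gen_discharge("spike", cfg)
    expect_true(attr(w, "duration_s") >= 0.020 &&
                  attr(w, "duration_s") <= 0.070)
    expect_gt(max(abs(w)), 50)
  }
  set.seed(2)
  for (k in 1:1000) {
    w <- gen_discharge("sharp", cfg)
    expect_true(attr(w, "duration_s") >= 0.070 &&
                  attr(w, "duration_s") <= 0.200)
    expect_true(max(abs(w)) >= 100 && max(abs(w)) <= 200)
  }
  set.seed(3)
  for (k in 1:50) {
    w <- gen_discharge("spike_rhythm", cfg)
    expect_gt(length(w) / cfg$fs, 1)
    expect_true(max(abs(w)) >= 100 && max(abs(w)) <= 200)
  }
  # slow-wave complexes end with a slow wave of higher amplitude than the
  # transient
  set.seed(4)
  for (st in c("spike_slow", "sharp_slow", "polyspike_slow")) {
    w <- gen_discharge(st, cfg)
    expect_gt(max(abs(w)), attr(w, "amplitude"))
  }
  expect_error(gen_discharge("wiggle", cfg), "unknown")
})

test_that("datasets reproduce the clinical composition and are seeded", {
  ds <- gen_dataset(cfg = generator_config(), seed = 1)
  expect_length(ds$epochs, 640)
  expect_equal(sum(ds$manifest$label == "normal"), 100)
  expect_equal(sum(ds$manifest$label == "epileptiform"), 540)
  expect_equal(sum(discharge_subtypes), 540)
  got <- table(ds$manifest$subtype[ds$manifest$label == "epileptiform"])
  expect_equal(as.vector(got[names(discharge_subtypes)]),
               as.vector(discharge_subtypes))
  small1 <- gen_dataset(4, 6, cfg = generator_config(), seed = 9)
  small2 <- gen_dataset(4, 6, cfg = generator_config(), seed = 9)
  expect_identical(lapply(small1$epochs, `[[`, "data"),
                   lapply(small2$epochs, `[[`, "data"))
  expect_identical(small1$manifest, small2$manifest)
})

test_that("datasets can round-trip through EDF files and a manifest", {
  dir <- withr::local_tempdir()
  ds <- gen_dataset(2, 3, cfg = generator_config(), seed = 31, out_dir = dir)
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 5)
  expect_true(all(file.exists(file.path(dir, man$source_file))))
  rec <- read_edf(file.path(dir, man$source_file[1]))
  expect_lt(max(abs(rec$signals - ds$epochs[[1]]$data)), 2000 / 65535)
})

test_that("the generated classes mirror the clinical feature contrast", {
  ft <- cached_features()
  m_psd <- tapply(ft$psd_energy, ft$label, mean)
  m_lam <- tapply(ft$lam1, ft$label, mean)
  expect_gt(m_psd[["epileptiform"]], m_psd[["normal"]])
  expect_lt(m_lam[["epileptiform"]], m_lam[["normal"]])
})
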