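test_that("Poisson spike trains are deterministic per seed with the right rate", {
  expect_length(generateSpikeTimes(0, 100, seed = 1), 0)
  a <- generateSpikeTimes(10, 100, seed = 5)
  b <- generateSpikeTimes(10, 100, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, generateSpikeTimes(10, 100, seed = 6)))
  # count within the 4-sigma Poisson band around 1000
  expect_gt(length(a), 1000 - 4 * sqrt(1000))
  expect_lt(length(a), 1000 + 4 * sqrt(1000))
  expect_true(!is.unsorted(a))
  expect_true(all(a >= 0 & a < 100))
})

test_that("unit footprints decay exponentially with site distance", {
  geom <- probeGeometry(40)                 # 4 x 10 patch
  unit <- geom[18, ]                        # on top of a site
  amp <- renderUnit(geom, unit, peakUv = 100, spatialDecayUm = 11.5)
  expect_equal(amp[18], 100)
  d <- sqrt(rowSums(sweep(geom, 2, unit)^2))
  expect_equal(amp, 100 * exp(-d / 11.5))
  expect_true(all(amp > 0))                 # every site of the patch sees it
  # at distance = decay constant the amplitude is peak / e
  away <- renderUnit(rbind(unit + c(11.5, 0)), unit, 100, 11.5)
  expect_equal(away, 100 / exp(1), ignore_attr = TRUE)
  # several sites above half peak once decay comfortably exceeds the pitch
  amp2 <- renderUnit(geom, unit, peakUv = 100, spatialDecayUm = 23)
  expect_gte(sum(amp2 > 50), 2)
  # strictly decreasing with distance
  o <- order(d)
  expect_true(all(diff(amp[o]) <= 0))
})

test_that("quantization is centered at mid-scale and saturates at the rails", {
  expect_equal(quantizeUv(0), 32768L)
  expect_equal(quantizeUv(0.195), 32769L)
  expect_equal(quantizeUv(-0.195), 32767L)
  expect_equal(quantizeUv(1e9), 65535L)
  expect_equal(quantizeUv(-1e9), 0L)
  expect_equal(dequantizeCode(quantizeUv(7.8)), 7.8, tolerance = 1e-6)
})

test_that("GPIO state updates at 2 kHz and holds for 15 samples", {
  expect_equal(gpioWords(30, 0xFFFF), rep(65535L, 30))
  expect_equal(gpioWords(30, 0), rep(0L, 30))
  # 1 kHz square wave on pin 0: toggles every alternate 2 kHz tick
  sq <- function(t) ifelse(floor(t * 2000) %% 2 == 0, 1, 0)
  w <- gpioWords(90, sq)
  expect_equal(w, rep(rep(c(1L, 0L), 3), each = 15))
  # hold phase respects the global sample ordinal
  w2 <- gpioWords(15, sq, startSample = 15)
  expect_equal(w2, rep(0L, 15))
  expect_error(gpioWords(10, function(t) 1e6), "16-bit")
})

test_that("generated sessions are byte-identical per (config, seed)", {
  cfg <- simConfig(nChips = 2, durationSamples = 300, nUnits = 2, seed = 9,
                   experimentId = 1443700000, moduleId = 12)
  f1 <- tempfile(); f2 <- tempfile()
  generateSession(cfg, f1)
  generateSession(cfg, f2)
  expect_true(diffSessions(f1, f2)$equal)
  # in-memory generation writes the identical stream
  f3 <- tempfile()
  writeSession(generateSession(cfg), f3)
  expect_true(diffSessions(f1, f3)$equal)
  # a different seed diverges
  cfg2 <- cfg; cfg2@seed <- 10
  f4 <- tempfile(); generateSession(cfg2, f4)
  expect_false(diffSessions(f1, f4)$equal)
})

test_that("dead chips clear their live bits and carry zero filler", {
  cfg <- simConfig(nChips = 3, deadChips = 1, durationSamples = 64, seed = 2)
  s <- generateSession(cfg)
  expect_equal(unique(chipLive(s)), 2^0 + 2^2)   # chips 0 and 2 live
  expect_true(all(neuralData(s)[33:64, ] == 0))  # chip 1 rows
  expect_true(any(neuralData(s)[1:32, ] != 0))
  expect_true(all(neuralData(s)[97:1024, ] == 0))  # unpopulated chips
})

test_that("sample indices roll over at exactly 2^32", {
  cfg <- simConfig(nChips = 1, durationSamples = 10, startIndex = 2^32 - 4,
                   seed = 1)
  s <- generateSession(cfg)
  expect_equal(sampleIndex(s),
               c(2^32 - 4, 2^32 - 3, 2^32 - 2, 2^32 - 1, 0, 1, 2, 3, 4, 5))
  expect_equal(unwrapIndices(sampleIndex(s)), (2^32 - 4) + 0:9)
})

test_that("the noise floor RMS matches the configured value", {
  cfg <- simConfig(nChips = 1, durationSamples = 20000, nUnits = 0,
                   noiseRmsUv = 3.9, seed = 14)
  s <- generateSession(cfg)
  uv <- dequantizeCode(neuralData(s)[1:32, ], cfg@lsbUv)
  expect_equal(sqrt(mean(uv^2)), 3.9, tolerance = 0.05)
  expect_lt(abs(mean(uv)), 0.1)
})

test_that("the GPIO word lands in the designated aux slot", {
  cfg <- simConfig(nChips = 1, durationSamples = 45, gpioPattern = 0x00A5,
                   gpioAuxChannel = 2, seed = 1)
  s <- generateSession(cfg)
  expect_equal(auxData(s)[3, ], rep(165L, 45))
  expect_true(all(auxData(s)[-3, ] == 0))
})

test_that("a high-SNR unit is recovered by threshold detection", {
  cfg <- simConfig(nChips = 1, durationSamples = 3 * 30000, nUnits = 1,
                   firingRateHz = 15, waveform = spikeTemplate(peakUv = 200),
                   unitPositions = matrix(c(11.5, 115), 1), seed = 33)
  f <- tempfile()
  res <- generateSession(cfg, f)
  amp <- renderUnit(cfg@geometry, res$unitPositions[1, ], 200,
                    cfg@spatialDecayUm)
  best <- which.max(amp)
  se <- extractChannels(f, best - 1)
  uv <- dequantizeCode(as.vector(SummarizedExperiment::assay(se)), cfg@lsbUv)
  below <- uv < -4 * cfg@noiseRmsUv
  onsets <- which(below & !c(FALSE, below[-length(below)]))
  detected <- sum(c(TRUE, diff(onsets) > length(cfg@waveform)))
  expected <- cfg@firingRateHz * 3
  expect_lt(abs(detected - expected), 4 * sqrt(expected))
  unlink(f)
})

test_that("configs load from YAML", {
  p <- tempfile(fileext = ".yaml")
  writeLines(c("nChips: 2", "durationSamples: 128", "seed: 7",
               "noiseRmsUv: 2.5", "gpioPattern: 165"), p)
  cfg <- simConfigFromYaml(p)
  expect_s4_class(cfg, "SimConfig")
  expect_equal(cfg@nChips, 2)
  expect_equal(cfg@noiseRmsUv, 2.5)
  writeLines(c("nChips: 2", "bogus: 1"), p)
  expect_error(simConfigFromYaml(p), "unknown config fields")
})

test_that("config validity rejects out-of-range parameters", {
  expect_error(simConfig(nChips = 33), "nChips")
  expect_error(simConfig(noiseRmsUv = -1), "noiseRmsUv")
  expect_error(simConfig(durationSamples = 0), "durationSamples")
  expect_error(simConfig(startIndex = 2^32), "startIndex")
})
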