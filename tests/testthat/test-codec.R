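test_that("record layout identities hold for the default format", {
  lay <- recordLayout()
  expect_equal(lay@metaBytes + lay@neuralBytes + lay@auxBytes + lay@padBytes,
               lay@recordBytes)
  expect_equal(lay@metaBytes, 20)
  expect_equal(lay@neuralBytes, 2048)
  expect_equal(lay@auxBytes, 192)
  expect_equal(lay@padBytes, 1836)
  expect_equal(lay@recordBytes, 4096)
  expect_equal(lay@blockBytes, 128 * 4096)
  expect_error(recordLayout(recordBytes = 2000), "exceed")
})

test_that("an all-zero sample encodes to an all-zero record", {
  rec <- encodeSample(moduleSession(n = 1, chipLive = 0))
  expect_length(rec, 4096)
  expect_true(all(rec == as.raw(0)))
})

test_that("every encoded record ends in 1836 zero bytes", {
  s <- randomSession(1, seed = 4)
  rec <- encodeSample(s)
  expect_length(rec, 4096)
  expect_true(all(rec[2261:4096] == as.raw(0)))
})

test_that("channel byte offsets follow the chip-major layout", {
  # independent oracle: channel c lives at bytes 20 + 2c, 20 + 2c + 1
  s <- moduleSession(n = 1, chipLive = 0)
  for (ch in c(0, 1, 31, 32, 512, 1023)) {
    s2 <- s
    s2@neural[ch + 1L, 1] <- 1L
    rec <- encodeSample(s2)
    expect_identical(which(rec != as.raw(0)) - 1L, as.integer(20 + 2 * ch))
  }
  # aux channel a lives after the 2048 neural bytes
  s3 <- s
  s3@aux[5, 1] <- 258L  # 0x0102 -> bytes 02 01 little-endian
  rec <- encodeSample(s3)
  off <- 20 + 2048 + 2 * 4
  expect_identical(which(rec != as.raw(0)) - 1L, as.integer(off + 0:1))
  expect_identical(as.integer(rec[off + 1:2]), c(2L, 1L))
})

test_that("decode inverts encode over randomized samples", {
  for (seed in 1:5) {
    s <- randomSession(1, seed = seed,
                       startIndex = sample(0:(2^31), 1),
                       experimentId = sample(1:2^31, 1),
                       moduleId = sample(0:(2^31), 1))
    expect_equal(decodeSample(encodeSample(s)), s)
  }
  # bulk: many random samples through the vectorized path
  s <- randomSession(200, seed = 99, startIndex = 2^32 - 100)
  f <- sessionFile(s)
  expect_equal(readSession(f), s)
})

test_that("strict padding mode rejects a dirty pad byte", {
  rec <- encodeSample(randomSession(1, seed = 2))
  expect_equal(decodeSample(rec, strictPadding = TRUE),
               decodeSample(rec))
  rec[4096] <- as.raw(1)
  expect_error(decodeSample(rec, strictPadding = TRUE), "padding")
  expect_s4_class(decodeSample(rec), "ModuleSession")  # lenient mode ignores
  expect_error(decodeSample(rec[-1]), "4096")
})

test_that("written sessions occupy exactly n x 4096 bytes, block-aligned", {
  s <- randomSession(300, seed = 7)  # 2 whole blocks + 44 trailing samples
  f <- sessionFile(s)
  expect_equal(file.size(f), 300 * 4096)
  expect_equal(file.size(f) %% 4096, 0)
  s128 <- randomSession(256, seed = 8)
  f2 <- sessionFile(s128)
  expect_equal(file.size(f2), 2 * 524288)
})

test_that("sessionSink emits whole blocks and flushes the tail on close", {
  f <- tempfile()
  sink <- sessionSink(f)
  sink$append(randomSession(100, seed = 1))
  expect_equal(sink$samplesWritten(), 0)  # below one block
  sink$append(randomSession(100, seed = 2, startIndex = 100))
  expect_equal(sink$samplesWritten(), 128)
  expect_equal(sink$close(), 200)
  expect_equal(file.size(f), 200 * 4096)
  # identity change mid-stream is a consistency error
  sink2 <- sessionSink(tempfile())
  sink2$append(randomSession(10, seed = 1, moduleId = 1))
  expect_error(sink2$append(randomSession(10, seed = 1, moduleId = 2)),
               "identity")
  sink2$close()
})

test_that("seekSample agrees with a full linear scan", {
  s <- randomSession(1000, seed = 12, startIndex = 2^32 - 500)
  f <- sessionFile(s)
  full <- readSession(f)
  for (k in c(0, 4, 617, 999)) {
    one <- seekSample(f, k)
    expect_equal(sampleIndex(one), sampleIndex(full)[k + 1])
    expect_equal(neuralData(one)[, 1], neuralData(full)[, k + 1])
  }
  expect_equal(sampleIndex(seekSample(f, 617)),
               (2^32 - 500 + 617) %% 2^32)
  expect_error(seekSample(f, 1000), "ordinal")
  expect_error(seekSample(f, -1), "ordinal")
})

test_that("a sub-record trailing remainder is reported and skipped", {
  s <- randomSession(5, seed = 3)
  f <- sessionFile(s)
  appendTail(f, 100)
  expect_warning(got <- readSession(f), class = "truncatedTail")
  expect_equal(nSamples(got), 5)
})

test_that("index unwrapping is exact across rollover", {
  expect_equal(unwrapIndices(c(5, 6, 7)), c(5, 6, 7))
  expect_equal(unwrapIndices(c(4294967294, 4294967295, 0, 1)),
               c(4294967294, 4294967295, 4294967296, 4294967297))
  # oracle: a plain 64-bit counter reduced mod 2^32
  set.seed(21)
  start <- 2^32 - sample(1:5, 1)
  truth <- start + 0:9
  expect_equal(unwrapIndices(truth %% 2^32), truth)
  expect_error(unwrapIndices(c(-1, 0)), "32-bit")
})

test_that("extractChannels pulls the right channels, keyed by unwrapped index", {
  s <- randomSession(50, seed = 31, startIndex = 2^32 - 25)
  f <- sessionFile(s)
  se <- extractChannels(f, c(0, 100, 1023, 1024, 1119))
  a <- SummarizedExperiment::assay(se, "adc")
  expect_equal(a["ch100", ], neuralData(s)[101, ], ignore_attr = TRUE)
  expect_equal(a["ch1024", ], auxData(s)[1, ], ignore_attr = TRUE)
  expect_equal(a["ch1119", ], auxData(s)[96, ], ignore_attr = TRUE)
  idx <- SummarizedExperiment::colData(se)$unwrappedIndex
  expect_equal(idx, (2^32 - 25) + 0:49)
  expect_error(extractChannels(f, 1120), "0..1119")
  # file path and in-memory agree
  expect_equal(SummarizedExperiment::assay(extractChannels(s, c(3, 1050))),
               SummarizedExperiment::assay(extractChannels(f, c(3, 1050))))
})

test_that("exported channels survive the CSV and binary round trips", {
  s <- randomSession(20, seed = 41)
  se <- extractChannels(s, c(2, 1025))
  prefix <- tempfile()
  paths <- exportChannels(se, prefix)
  csv <- utils::read.csv(paste0(prefix, ".csv"), check.names = FALSE)
  expect_equal(csv[["ch2"]], neuralData(s)[3, ])
  expect_equal(csv[["unwrapped_index"]], 0:19)
  bin <- readBin(paste0(prefix, "_ch2.i16"), "integer", n = 20, size = 2,
                 signed = FALSE, endian = "little")
  expect_equal(bin, neuralData(s)[3, ])
  sidecar <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(sidecar$n_samples, 20)
})
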