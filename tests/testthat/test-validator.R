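# The integrity procedure: pristine sessions pass; each fault kind is
# detected exactly once at the injected 0-based record ordinal; rollover of
# the 32-bit counter is not a skip.

test_that("pristine generated sessions pass, for a range of configs", {
  for (seed in 1:3) {
    cfg <- simConfig(nChips = sample(1:4, 1), durationSamples = 200 + 7 * seed,
                     nUnits = seed - 1, seed = seed,
                     deadChips = if (seed == 3) 0 else numeric(0),
                     experimentId = 1443700000 + seed, moduleId = seed)
    f <- tempfile()
    generateSession(cfg, f)
    rep <- validateSession(f, expectedBytes = file.size(f))
    expect_true(passed(rep))
    expect_equal(nrow(validationErrors(rep)), 0)
    expect_equal(rep@nRecords, cfg@durationSamples)
    expect_equal(rep@experimentId, cfg@experimentId)
    unlink(f)
  }
})

test_that("a removed record yields exactly one INDEX_SKIP at its ordinal", {
  f <- sessionFile(randomSession(5000, seed = 1, startIndex = 100))
  dropRecord(f, 1000)
  rep <- validateSession(f)
  expect_false(passed(rep))
  e <- validationErrors(rep)
  expect_equal(nrow(e), 1)
  expect_equal(e$kind, "INDEX_SKIP")
  expect_equal(e$recordOrdinal, 1000)
  expect_match(e$detail, "expected 1100, found 1101")
  unlink(f)
})

test_that("a duplicated record yields exactly one INDEX_REPEAT", {
  f <- sessionFile(randomSession(600, seed = 2))
  duplicateRecord(f, 250)
  rep <- validateSession(f)
  e <- validationErrors(rep)
  expect_equal(nrow(e), 1)
  expect_equal(e$kind, "INDEX_REPEAT")
  expect_equal(e$recordOrdinal, 251)
  unlink(f)
})

test_that("an identifier change is pinned to its record", {
  f <- sessionFile(randomSession(300, seed = 3))
  # module id lives at bytes 8..11 of the record
  setFileByte(f, 77 * 4096 + 8, 0xAB)
  rep <- validateSession(f)
  e <- errorsOfKind(rep, "ID_CHANGE")
  expect_equal(nrow(e), 1)
  expect_equal(e$recordOrdinal, 77)
  unlink(f)
  # a chip-live change is an identity error too, unless allowed
  f2 <- sessionFile(randomSession(300, seed = 4))
  setFileByte(f2, 120 * 4096 + 16, 0x00)  # clear low mask byte
  rep2 <- validateSession(f2)
  e2 <- errorsOfKind(rep2, "ID_CHANGE")
  expect_equal(nrow(e2), 1)
  expect_equal(e2$recordOrdinal, 120)
  expect_true(passed(validateSession(f2, allowChipLiveChange = TRUE)))
  unlink(f2)
})

test_that("a dirty padding byte is pinned to its record", {
  f <- sessionFile(randomSession(300, seed = 5))
  setFileByte(f, 42 * 4096 + 4000, 0x01)
  rep <- validateSession(f)
  e <- validationErrors(rep)
  expect_equal(nrow(e), 1)
  expect_equal(e$kind, "NONZERO_PADDING")
  expect_equal(e$recordOrdinal, 42)
  unlink(f)
})

test_that("a sub-record tail and a size mismatch are reported", {
  f <- sessionFile(randomSession(200, seed = 6))
  appendTail(f, 1000)
  rep <- validateSession(f)
  e <- validationErrors(rep)
  expect_equal(e$kind, "TRUNCATED_TAIL")
  expect_equal(e$recordOrdinal, 200)
  expect_equal(rep@remainderBytes, 1000)
  unlink(f)
  f2 <- sessionFile(randomSession(200, seed = 7))
  rep2 <- validateSession(f2, expectedBytes = 205 * 4096)
  expect_equal(validationErrors(rep2)$kind, "SIZE_MISMATCH")
  expect_true(passed(validateSession(f2, expectedBytes = 200 * 4096 + 99)))
  unlink(f2)
})

test_that("index rollover is not a skip", {
  f <- sessionFile(randomSession(1000, seed = 8, startIndex = 2^32 - 500))
  rep <- validateSession(f)
  expect_true(passed(rep))
  expect_equal(rep@firstIndexRaw, 2^32 - 500)
  expect_equal(rep@lastIndexRaw, 499)
  expect_equal(rep@lastIndexUnwrapped, 2^32 - 500 + 999)
  # but a skip across the rollover is still caught
  dropRecord(f, 500)  # the record holding index 0
  rep2 <- validateSession(f)
  e <- validationErrors(rep2)
  expect_equal(e$kind, "INDEX_SKIP")
  expect_equal(e$recordOrdinal, 500)
  unlink(f)
})

test_that("multiple faults are all censused (no fail-fast)", {
  f <- sessionFile(randomSession(400, seed = 9))
  setFileByte(f, 10 * 4096 + 4095, 0x02)   # padding
  dropRecord(f, 200)                        # skip
  rep <- validateSession(f)
  e <- validationErrors(rep)
  expect_equal(nrow(e), 2)
  expect_setequal(e$kind, c("NONZERO_PADDING", "INDEX_SKIP"))
  unlink(f)
})

test_that("reports render as text and JSON with stable fields", {
  f <- sessionFile(randomSession(10, seed = 10))
  rep <- validateSession(f)
  txt <- summarizeReport(rep)
  expect_true(any(grepl("PASSED", txt)))
  js <- jsonlite::fromJSON(summarizeReport(rep, json = TRUE))
  expect_true(js$passed)
  expect_equal(js$n_records, 10)
  expect_equal(validationExitCode(rep), 0)
  dropRecord(f, 5)
  rep2 <- validateSession(f)
  expect_equal(validationExitCode(rep2), 1)
  js2 <- jsonlite::fromJSON(summarizeReport(rep2, json = TRUE))
  expect_equal(js2$errors$kind, "INDEX_SKIP")
  unlink(f)
  expect_error(validateSession(tempfile()), "cannot read")
})

test_that("diffSessions pinpoints the first divergent record", {
  s <- randomSession(300, seed = 11)
  fa <- sessionFile(s); fb <- sessionFile(s)
  expect_true(diffSessions(fa, fb)$equal)
  setFileByte(fb, 123 * 4096 + 500, 0x7F)
  d <- diffSessions(fa, fb)
  expect_false(d$equal)
  expect_equal(d$firstDivergence, 123)
  # length mismatch diverges at the shorter length
  fc <- sessionFile(s[1:200])
  d2 <- diffSessions(fa, fc)
  expect_false(d2$equal)
  expect_equal(d2$firstDivergence, 200)
  unlink(c(fa, fb, fc))
})
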