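# Fixture builders: sessions with randomized payloads and byte-level
# corruption helpers for fault injection. All fixtures are generated in
# code at test time; record ordinals are 0-based throughout.

randomSession <- function(n, seed = 1, startIndex = 0,
                          experimentId = 1443700000, moduleId = 77,
                          chipLive = 2^32 - 1) {
  set.seed(seed)
  moduleSession(
    experimentId = experimentId, moduleId = moduleId,
    startIndex = startIndex, chipLive = chipLive,
    neural = matrix(sample(0:65535, 1024 * n, replace = TRUE), 1024, n),
    aux = matrix(sample(0:65535, 96 * n, replace = TRUE), 96, n))
}

sessionFile <- function(session) {
  f <- tempfile(fileext = ".dat")
  writeSession(session, f)
  f
}

readRawFile <- function(path) readBin(path, "raw", n = file.size(path))

writeRawFile <- function(bytes, path) {
  con <- file(path, "wb")
  writeBin(bytes, con)
  close(con)
  path
}

# remove record k (0-based) from a session file
dropRecord <- function(path, k, rb = 4096) {
  r <- readRawFile(path)
  writeRawFile(r[-((k * rb + 1):((k + 1) * rb))], path)
}

# duplicate record k in place
duplicateRecord <- function(path, k, rb = 4096) {
  r <- readRawFile(path)
  rec <- r[(k * rb + 1):((k + 1) * rb)]
  writeRawFile(append(r, rec, after = (k + 1) * rb), path)
}

# overwrite one byte at 0-based file offset
setFileByte <- function(path, offset, value) {
  con <- file(path, "r+b")
  seek(con, where = offset, rw = "write")
  writeBin(as.raw(value), con)
  close(con)
  path
}

# append n bytes of zeros (a sub-record tail)
appendTail <- function(path, n) {
  con <- file(path, "ab")
  writeBin(raw(n), con)
  close(con)
  path
}

errorsOfKind <- function(report, kind) {
  e <- validationErrors(report)
  e[e$kind == kind, , drop = FALSE]
}
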