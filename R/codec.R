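# Byte-level codec for the raw sequential stream. One complete module sample
# encodes as exactly one fixed-size record:
#
#   offset 0    20 B  metadata: experiment id (u64) | module id (u32) |
#                     sample index (u32) | chip live mask (u32)
#   offset 20   2048 B  neural words, chip-major (chip 0 ch 0..31, chip 1, ...)
#   offset 2068 192 B   aux words, chip-major (3 per chip)
#   offset 2260 1836 B  zero padding
#
# All fields little-endian. Every offset is word-aligned, so the codec works
# on 16-bit words throughout.

# ModuleSession columns -> raw vector of n * recordBytes bytes
sessionToRaw <- function(x) {
  lay <- x@layout
  n <- nSamples(x)
  wordsPerRecord <- lay@recordBytes / 2
  metaWords <- lay@metaBytes / 2
  nn <- nNeuralChannels(lay)
  na <- nAuxChannels(lay)
  W <- matrix(0L, wordsPerRecord, n)
  if (n > 0) {
    W[1:4, ] <- as.integer(u64ToWords(rep(x@experimentId, n)))
    W[5:6, ] <- as.integer(u32ToWords(rep(x@moduleId, n)))
    W[7:8, ] <- as.integer(u32ToWords(x@sampleIndex))
    W[9:10, ] <- as.integer(u32ToWords(x@chipLive))
    W[metaWords + seq_len(nn), ] <- x@neural
    W[metaWords + nn + seq_len(na), ] <- x@aux
  }
  wordsToRaw(W)
}

# raw vector (multiple of recordBytes) -> ModuleSession; identity metadata is
# taken from the first record (the validator, not the decoder, polices
# mid-stream identity changes).
rawToSession <- function(r, layout = recordLayout(), strictPadding = FALSE) {
  rb <- layout@recordBytes
  if (length(r) %% rb != 0)
    stop("byte length ", length(r), " is not a multiple of the ", rb, "-byte record")
  n <- length(r) %/% rb
  W <- matrix(rawToWords(r), rb / 2, n)
  metaWords <- layout@metaBytes / 2
  nn <- nNeuralChannels(layout)
  na <- nAuxChannels(layout)
  if (strictPadding && n > 0) {
    pad <- W[(metaWords + nn + na + 1):(rb / 2), , drop = FALSE]
    bad <- which(colSums(pad != 0L) > 0L)
    if (length(bad))
      stop("corrupt record: nonzero padding in record ordinal ", bad[1] - 1L)
  }
  expId <- if (n > 0) wordsToU64(W[1, 1], W[2, 1], W[3, 1], W[4, 1]) else 0
  modId <- if (n > 0) wordsToU32(W[5, 1], W[6, 1]) else 0
  new("ModuleSession", experimentId = expId, moduleId = modId,
      sampleIndex = wordsToU32(W[7, ], W[8, ]),
      chipLive = wordsToU32(W[9, ], W[10, ]),
      neural = W[metaWords + seq_len(nn), , drop = FALSE],
      aux = W[metaWords + nn + seq_len(na), , drop = FALSE],
      layout = layout)
}

#' Encode and decode single on-disk records
#'
#' `encodeSample()` serializes a one-sample [ModuleSession-class] into its
#' exact on-disk record: 20 metadata bytes, 2048 neural bytes, 192 aux
#' bytes, then zero padding to 4096 bytes, all little-endian.
#' `decodeSample()` is its inverse; `decodeSample(encodeSample(s))`
#' reproduces `s` bit-exactly.
#'
#' @param sample a [ModuleSession-class] with exactly one sample.
#' @param record a raw vector of exactly `recordBytes` (4096) bytes.
#' @param layout the [RecordLayout-class] to decode under.
#' @param strictPadding if `TRUE`, nonzero bytes in the padding section
#'   raise a corruption error; otherwise padding content is ignored.
#' @return `encodeSample()`: a raw vector of `recordBytes` bytes;
#'   `decodeSample()`: a one-sample [ModuleSession-class].
#' @examples
#' s <- moduleSession(experimentId = 1443700000, moduleId = 77, n = 1)
#' rec <- encodeSample(s)
#' length(rec)  # 4096
#' identical(sampleIndex(decodeSample(rec)), sampleIndex(s))
#' @export
encodeSample <- function(sample) {
  if (nSamples(sample) != 1L)
    stop("encodeSample() takes a single sample; use writeSession() for streams")
  sessionToRaw(sample)
}

#' @rdname encodeSample
#' @export
decodeSample <- function(record, strictPadding = FALSE, layout = recordLayout()) {
  if (length(record) != layout@recordBytes)
    stop("record must be exactly ", layout@recordBytes, " bytes, got ", length(record))
  rawToSession(record, layout, strictPadding = strictPadding)
}

#' Streaming block writer for session files
#'
#' The hardware collects sets of 128 complete module samples and writes each
#' set to the drive as one block. `sessionSink()` reproduces that contract
#' for incremental writers: appended samples are buffered and emitted in
#' whole 128-sample blocks only; a trailing partial block is flushed as a
#' final short block on `close()`. The byte stream contains no headers or
#' separators. An experiment/module identity change between appended chunks
#' raises a consistency error.
#'
#' @param path output file path.
#' @param layout a [RecordLayout-class].
#' @return a list with functions `append(session)`, `close()` (returns the
#'   total sample count written) and `samplesWritten()`.
#' @seealso [writeSession()] for the one-shot form.
#' @export
sessionSink <- function(path, layout = recordLayout()) {
  con <- file(path, "wb")
  buf <- NULL        # pending partial-block session
  identity <- NULL
  written <- 0
  blockN <- layout@blockSamples
  flushBlocks <- function(final = FALSE) {
    n <- nSamples(buf)
    emit <- if (final) n else (n %/% blockN) * blockN
    if (emit > 0) {
      writeBin(sessionToRaw(buf[seq_len(emit)]), con)
      written <<- written + emit
      buf <<- if (emit < n) buf[(emit + 1):n] else NULL
    }
  }
  list(
    append = function(session) {
      id <- list(experimentId = session@experimentId, moduleId = session@moduleId)
      if (is.null(identity)) identity <<- id else checkSameIdentity(identity, id)
      buf <<- if (is.null(buf)) session else
        initialize(buf,
                   sampleIndex = c(buf@sampleIndex, session@sampleIndex),
                   chipLive = c(buf@chipLive, session@chipLive),
                   neural = cbind(buf@neural, session@neural),
                   aux = cbind(buf@aux, session@aux))
      flushBlocks()
      invisible(written)
    },
    close = function() {
      if (!is.null(buf)) flushBlocks(final = TRUE)
      close(con)
      written
    },
    samplesWritten = function() written)
}

#' Write a session to a raw sequential file
#'
#' One-shot wrapper around [sessionSink()]: encodes every sample and writes
#' the stream in whole 128-sample blocks, flushing any trailing partial
#' block on close. A session of N whole blocks occupies exactly
#' `N * 524288` bytes.
#'
#' @param session a [ModuleSession-class].
#' @param path output file path.
#' @return invisibly, the number of samples written.
#' @export
writeSession <- function(session, path) {
  sink <- sessionSink(path, session@layout)
  sink$append(session)
  invisible(sink$close())
}

#' Read a session file
#'
#' `readSession()` decodes a whole raw sequential session file into memory.
#' `readSessionChunks()` is the constant-memory form: it scans the file in
#' bounded chunks and calls `fun(chunk, firstOrdinal)` with successive
#' [ModuleSession-class] pieces (`firstOrdinal` is the 0-based record
#' ordinal of the chunk's first sample). Both accept files whose length is
#' any multiple of the record size; a trailing remainder shorter than one
#' record is legal (the drive filled mid-record), reported via a
#' `truncatedTail` warning and skipped.
#'
#' @param path session file path.
#' @param layout a [RecordLayout-class].
#' @param fun callback `function(session, firstOrdinal)`; a return of
#'   `FALSE` stops the scan early.
#' @param chunkRecords records per chunk (default 1024, 4 MiB).
#' @return `readSession()`: a [ModuleSession-class]. `readSessionChunks()`:
#'   invisibly, a list with `nRecords` and `remainderBytes`.
#' @export
readSession <- function(path, layout = recordLayout()) {
  pieces <- list()
  readSessionChunks(path, function(chunk, first) {
    pieces[[length(pieces) + 1L]] <<- chunk
    TRUE
  }, layout = layout)
  if (length(pieces) == 0L) return(moduleSession(n = 0, layout = layout))
  out <- pieces[[1L]]
  if (length(pieces) > 1L)
    out <- initialize(out,
      sampleIndex = unlist(lapply(pieces, sampleIndex)),
      chipLive = unlist(lapply(pieces, chipLive)),
      neural = do.call(cbind, lapply(pieces, neuralData)),
      aux = do.call(cbind, lapply(pieces, auxData)))
  out
}

#' @rdname readSession
#' @export
readSessionChunks <- function(path, fun, layout = recordLayout(),
                              chunkRecords = 1024L) {
  rb <- layout@recordBytes
  bytes <- file.size(path)
  if (is.na(bytes)) stop("cannot read session file: ", path)
  nRecords <- bytes %/% rb
  remainder <- bytes %% rb
  con <- file(path, "rb")
  on.exit(close(con))
  done <- 0
  while (done < nRecords) {
    take <- min(chunkRecords, nRecords - done)
    r <- readBin(con, "raw", n = take * rb)
    chunk <- rawToSession(r, layout)
    keep <- fun(chunk, done)
    done <- done + take
    if (identical(keep, FALSE)) break
  }
  if (remainder > 0)
    warning(warningCondition(
      sprintf("session file has a truncated %d-byte trailing remainder (skipped)",
              remainder),
      class = "truncatedTail"))
  invisible(list(nRecords = nRecords, remainderBytes = remainder))
}

#' Random access to one record of a session file
#'
#' Fixed-size records permit O(1) access: record `k` starts at byte
#' `k * 4096`. Equivalent to the k-th element of a full [readSession()]
#' scan.
#'
#' @param path session file path.
#' @param k 0-based record ordinal, `0 <= k < floor(bytes / 4096)`.
#' @param layout a [RecordLayout-class].
#' @return a one-sample [ModuleSession-class].
#' @export
seekSample <- function(path, k, layout = recordLayout()) {
  rb <- layout@recordBytes
  n <- file.size(path) %/% rb
  if (is.na(n)) stop("cannot read session file: ", path)
  if (k < 0 || k >= n || k != floor(k))
    stop("record ordinal must be an integer in [0, ", n, "), got ", k)
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, where = k * rb)
  rawToSession(readBin(con, "raw", n = rb), layout)
}

#' Unwrap 32-bit sample counters onto a 64-bit axis
#'
#' The per-sample sequence counter is 32 bits wide and rolls over to zero
#' after about 39 h at 30 kS/s. Given raw counters whose consecutive values
#' increment by 1 modulo 2^32, returns the strictly increasing unwrapped
#' sequence starting at the first raw value.
#'
#' @param indices numeric vector of raw 32-bit counters.
#' @return numeric vector of unwrapped counters (exact 64-bit integers as
#'   doubles; exact below 2^53).
#' @examples
#' unwrapIndices(c(4294967294, 4294967295, 0, 1))
#' @export
unwrapIndices <- function(indices) {
  stopifnotU32(indices, "sample indices")
  n <- length(indices)
  if (n == 0L) return(numeric(0))
  d <- (diff(indices)) %% 2^32
  indices[1] + c(0, cumsum(d))
}
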