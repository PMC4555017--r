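# Post-acquisition integrity check: a single constant-memory pass over a
# stored session verifying that it is complete and correctly tagged — the
# identifiers never change, the sample index increments by exactly 1 modulo
# 2^32 without skipping or repeating, the padding is all zero, and the
# amount of data matches the storage that held it. Every violation is
# recorded with its 0-based record ordinal; validation continues to the end
# (full forensic census) rather than failing fast.

#' Validate the integrity of a stored session
#'
#' @param path session file path.
#' @param expectedBytes optional expected storage size in bytes (for
#'   example the drive capacity); a `SIZE_MISMATCH` error is recorded when
#'   `floor(expectedBytes / 4096)` disagrees with the record count.
#' @param allowChipLiveChange if `FALSE` (default) a mid-session change of
#'   the chip-live mask is reported under `ID_CHANGE`; set `TRUE` to permit
#'   chips dropping out mid-session.
#' @param layout a [RecordLayout-class].
#' @return a [ValidationReport-class]. An unreadable file raises an error
#'   (distinct from a failed report).
#' @examples
#' f <- tempfile()
#' generateSession(simConfig(nChips = 1, durationSamples = 256, seed = 3), f)
#' passed(validateSession(f))
#' @export
validateSession <- function(path, expectedBytes = NULL,
                            allowChipLiveChange = FALSE,
                            layout = recordLayout()) {
  if (!file.exists(path)) stop("cannot read session file: ", path)
  rb <- layout@recordBytes
  metaWords <- layout@metaBytes / 2
  payloadWords <- metaWords + nNeuralChannels(layout) + nAuxChannels(layout)
  wordsPerRecord <- rb / 2

  errs <- list()
  addErr <- function(kind, ordinal, detail)
    errs[[length(errs) + 1L]] <<- data.frame(
      kind = kind, recordOrdinal = ordinal, detail = detail)

  state <- new.env(parent = emptyenv())
  state$first <- NULL

  scan <- withCallingHandlers(
    readSessionChunks(path, function(chunk, firstOrdinal) {
      n <- nSamples(chunk)
      ords <- firstOrdinal + seq_len(n) - 1
      if (is.null(state$first)) {
        state$first <- list(expId = chunk@experimentId,
                            modId = chunk@moduleId,
                            mask = chunk@chipLive[1],
                            firstIdx = chunk@sampleIndex[1])
        state$prevIdx <- chunk@sampleIndex[1]
        state$prevOrd <- firstOrdinal
        startAt <- 2L
      } else startAt <- 1L
      idx <- chunk@sampleIndex
      prev <- c(state$prevIdx, idx)[seq_len(n)]
      if (startAt <= n) {
        d <- (idx[startAt:n] - prev[startAt:n]) %% 2^32
        for (j in which(d != 1)) {
          o <- ords[startAt + j - 1L]
          kind <- if (d[j] == 0) "INDEX_REPEAT" else "INDEX_SKIP"
          addErr(kind, o, sprintf("expected %s, found %s",
            format((prev[startAt + j - 1L] + 1) %% 2^32, scientific = FALSE),
            format(idx[startAt + j - 1L], scientific = FALSE)))
        }
      }
      badMask <- which(chunk@chipLive != state$first$mask)
      if (!allowChipLiveChange && length(badMask))
        for (j in badMask)
          addErr("ID_CHANGE", ords[j],
                 sprintf("chip_live changed: 0x%s -> 0x%s",
                         hex32(state$first$mask),
                         hex32(chunk@chipLive[j])))
      state$prevIdx <- idx[n]
      state$lastIdx <- idx[n]
      state$mask <- chunk@chipLive[n]
      TRUE
    }, layout = layout),
    truncatedTail = function(w) invokeRestart("muffleWarning"))

  # second structural pass over raw bytes for per-record ids and padding
  # (kept separate from the decode pass for clarity; both are single
  # sequential scans in bounded chunks)
  con <- file(path, "rb")
  on.exit(close(con))
  chunkRecords <- 1024L
  done <- 0
  firstIds <- NULL
  while (done < scan$nRecords) {
    take <- min(chunkRecords, scan$nRecords - done)
    W <- matrix(rawToWords(readBin(con, "raw", n = take * rb)),
                wordsPerRecord, take)
    expId <- wordsToU64(W[1, ], W[2, ], W[3, ], W[4, ])
    modId <- wordsToU32(W[5, ], W[6, ])
    if (is.null(firstIds)) firstIds <- list(expId = expId[1], modId = modId[1])
    badId <- which(expId != firstIds$expId | modId != firstIds$modId)
    for (j in badId)
      addErr("ID_CHANGE", done + j - 1L,
             sprintf("experiment/module id changed (%s/%s -> %s/%s)",
                     format(firstIds$expId, scientific = FALSE),
                     format(firstIds$modId, scientific = FALSE),
                     format(expId[j], scientific = FALSE),
                     format(modId[j], scientific = FALSE)))
    if (payloadWords < wordsPerRecord) {
      pad <- W[(payloadWords + 1):wordsPerRecord, , drop = FALSE]
      badPad <- which(colSums(pad != 0) > 0)
      for (j in badPad)
        addErr("NONZERO_PADDING", done + j - 1L,
               sprintf("%d nonzero padding word(s)", sum(pad[, j] != 0)))
    }
    done <- done + take
  }

  bytes <- file.size(path)
  if (scan$remainderBytes > 0)
    addErr("TRUNCATED_TAIL", scan$nRecords,
           sprintf("%d trailing bytes do not form a whole record",
                   scan$remainderBytes))
  if (!is.null(expectedBytes) && expectedBytes %/% rb != scan$nRecords)
    addErr("SIZE_MISMATCH", scan$nRecords,
           sprintf("expected %s records for %s bytes, found %s",
                   format(expectedBytes %/% rb, scientific = FALSE),
                   format(expectedBytes, scientific = FALSE),
                   format(scan$nRecords, scientific = FALSE)))

  errors <- if (length(errs)) do.call(rbind, errs) else
    data.frame(kind = character(0), recordOrdinal = numeric(0),
               detail = character(0))
  errors <- errors[order(errors$recordOrdinal, errors$kind), , drop = FALSE]
  rownames(errors) <- NULL
  firstIdx <- if (is.null(state$first)) NA_real_ else state$first$firstIdx
  lastIdx <- if (is.null(state$first)) NA_real_ else state$lastIdx
  # unwrapped span assumes at most one rollover between the end points; the
  # raw values are authoritative when the census is non-empty
  span <- if (scan$nRecords > 0) (lastIdx - firstIdx) %% 2^32 else NA_real_
  new("ValidationReport",
      nRecords = scan$nRecords, bytes = bytes,
      remainderBytes = scan$remainderBytes,
      firstIndexRaw = firstIdx, lastIndexRaw = lastIdx,
      firstIndexUnwrapped = firstIdx,
      lastIndexUnwrapped = if (is.na(span)) NA_real_ else firstIdx + span,
      experimentId = if (is.null(firstIds)) NA_real_ else firstIds$expId,
      moduleId = if (is.null(firstIds)) NA_real_ else firstIds$modId,
      errors = errors, passed = nrow(errors) == 0L)
}

#' @describeIn ValidationReport-accessors `TRUE` iff no errors were found.
#' @export
setMethod("passed", "ValidationReport", function(x) x@passed)

#' Accessors for validation reports
#' @param x a [ValidationReport-class].
#' @name ValidationReport-accessors
NULL

#' @describeIn ValidationReport-accessors the error census data.frame.
#' @export
setMethod("validationErrors", "ValidationReport", function(x) x@errors)

setMethod("show", "ValidationReport", function(object) {
  cat(summarizeReport(object), sep = "\n")
})

#' Render a validation report
#'
#' `summarizeReport()` renders a [ValidationReport-class] as stable
#' human-readable lines or as a JSON string with stable field names.
#' `validationExitCode()` maps a report to the process exit convention:
#' 0 pass, 1 fail (I/O problems surface as R errors, mapped to 2 by the
#' command-line driver).
#'
#' @param report a [ValidationReport-class].
#' @param json return a JSON string instead of text lines.
#' @return character vector of lines, or a JSON string.
#' @export
summarizeReport <- function(report, json = FALSE) {
  if (json) {
    return(as.character(jsonlite::toJSON(list(
      passed = report@passed,
      n_records = report@nRecords,
      bytes = report@bytes,
      remainder_bytes = report@remainderBytes,
      experiment_id = report@experimentId,
      module_id = report@moduleId,
      first_index = report@firstIndexRaw,
      last_index = report@lastIndexRaw,
      first_index_unwrapped = report@firstIndexUnwrapped,
      last_index_unwrapped = report@lastIndexUnwrapped,
      n_errors = nrow(report@errors),
      errors = report@errors), auto_unbox = TRUE, digits = NA, na = "null")))
  }
  c(sprintf("session: %s records (%s bytes, %d-byte remainder)",
            format(report@nRecords, scientific = FALSE),
            format(report@bytes, scientific = FALSE),
            report@remainderBytes),
    sprintf("ids: experiment %s, module %s",
            format(report@experimentId, scientific = FALSE),
            format(report@moduleId, scientific = FALSE)),
    sprintf("index: %s .. %s",
            format(report@firstIndexRaw, scientific = FALSE),
            format(report@lastIndexRaw, scientific = FALSE)),
    if (report@passed) "PASSED: no errors" else
      c(sprintf("FAILED: %d error(s)", nrow(report@errors)),
        sprintf("  [%s] record %s: %s", report@errors$kind,
                format(report@errors$recordOrdinal, scientific = FALSE),
                report@errors$detail)))
}

#' @rdname summarizeReport
#' @export
validationExitCode <- function(report) {
  if (report@passed) 0L else 1L
}

#' Compare two session files record by record
#'
#' Byte-exact comparison at record granularity, the copy-verification step
#' after downloading a drive's contents: returns an equality certificate or
#' the first divergent record ordinal. Files of different record counts
#' diverge at ordinal `min(nA, nB)` (the first record present in only one
#' file).
#'
#' @param pathA,pathB session file paths.
#' @param layout a [RecordLayout-class].
#' @return list with `equal`, `firstDivergence` (0-based ordinal or `NA`),
#'   `nRecordsA`, `nRecordsB`.
#' @export
diffSessions <- function(pathA, pathB, layout = recordLayout()) {
  rb <- layout@recordBytes
  nA <- file.size(pathA) %/% rb
  nB <- file.size(pathB) %/% rb
  if (is.na(nA) || is.na(nB)) stop("cannot read session file")
  conA <- file(pathA, "rb"); on.exit(close(conA), add = TRUE)
  conB <- file(pathB, "rb"); on.exit(close(conB), add = TRUE)
  common <- min(nA, nB)
  chunkRecords <- 1024L
  done <- 0
  while (done < common) {
    take <- min(chunkRecords, common - done)
    a <- readBin(conA, "raw", n = take * rb)
    b <- readBin(conB, "raw", n = take * rb)
    if (!identical(a, b)) {
      neq <- which(a != b)[1]
      return(list(equal = FALSE,
                  firstDivergence = done + (neq - 1) %/% rb,
                  nRecordsA = nA, nRecordsB = nB))
    }
    done <- done + take
  }
  if (nA != nB)
    return(list(equal = FALSE, firstDivergence = common,
                nRecordsA = nA, nRecordsB = nB))
  list(equal = TRUE, firstDivergence = NA_real_,
       nRecordsA = nA, nRecordsB = nB)
}
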