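# Multi-module scaling. Each module is an independent 1024-channel unit;
# recording more channels means running several modules in the same
# acquisition session and recombining their streams offline. Two timing
# regimes are simulated: free-running module clocks, whose relative skew
# grows linearly with elapsed time at the drift difference (ppm), and a
# shared sample-start pulse distributed to every module at the start of
# each 30 kHz sample, under which drift never accumulates and skew stays
# bounded by latch delay spread plus edge jitter — well within a sample
# period. Merging keys records on (experiment id, unwrapped sample index);
# no cross-correlation alignment is attempted.

#' Construct a module clock
#'
#' @param nominalRate nominal sample rate (samples/s).
#' @param driftPpm frequency error, parts per million.
#' @param jitterS per-edge timing noise standard deviation (s).
#' @param latchDelayS fixed pulse-to-sample latch delay (s).
#' @return a [ModuleClock-class].
#' @examples
#' moduleClock(driftPpm = 50, jitterS = 100e-9)
#' @export
moduleClock <- function(nominalRate = 30000, driftPpm = 0, jitterS = 0,
                        latchDelayS = 0) {
  new("ModuleClock", nominalRate = nominalRate, driftPpm = driftPpm,
      jitterS = jitterS, latchDelayS = latchDelayS)
}

setMethod("show", "ModuleClock", function(object) {
  cat(sprintf("ModuleClock: %g S/s, drift %+g ppm, jitter %g s, latch %g s\n",
              object@nominalRate, object@driftPpm, object@jitterS,
              object@latchDelayS))
})

#' Simulate per-module sample times
#'
#' Computes when each module latches sample `k` under one of three timing
#' regimes:
#' \describe{
#'   \item{`PULSED`}{a master source distributes a sample-start pulse at
#'     the beginning of every sample period; each module latches at
#'     `k / masterRate + latchDelay + jitter`. Drift never accumulates.}
#'   \item{`START_ONLY`}{a single start pulse aligns `k = 0`; afterwards
#'     each module free-runs at its own drifted rate.}
#'   \item{`FREE`}{no shared pulse at all; identical in form to
#'     `START_ONLY` with a common `t = 0`, kept distinct so the two
#'     readings of the scaling scheme can be compared by name.}
#' }
#' Under the free-running regimes sample `k` falls at
#' `k / (rate * (1 + drift)) + latchDelay + jitter`, so pairwise skew grows
#' linearly at the drift difference.
#'
#' Sample times are a closed form in `k`, so the matrix can be evaluated
#' exactly on any subset of ordinals (`ordinals`) without simulating the
#' samples in between.
#'
#' @param clocks list of [ModuleClock-class] objects, one per module.
#' @param nSamples number of samples in the run.
#' @param mode `"PULSED"`, `"START_ONLY"` or `"FREE"`.
#' @param seed RNG seed for the jitter draws.
#' @param ordinals 0-based sample ordinals to evaluate (default all).
#' @param masterRate pulse rate of the master source (PULSED mode).
#' @return numeric matrix, `length(ordinals) x length(clocks)`, of sample
#'   times in seconds; ordinals as rownames.
#' @examples
#' cl <- list(moduleClock(), moduleClock(driftPpm = 50))
#' ts <- simulateTimestamps(cl, nSamples = 30000, mode = "FREE", seed = 1)
#' max(maxSkew(ts))  # ~ 50e-6 * 1 s
#' @export
simulateTimestamps <- function(clocks, nSamples, mode = c("PULSED", "START_ONLY", "FREE"),
                               seed = 0, ordinals = NULL, masterRate = 30000) {
  mode <- match.arg(mode)
  if (length(clocks) == 0) stop("clocks must be a non-empty list")
  if (is.null(ordinals)) ordinals <- seq_len(nSamples) - 1
  if (any(ordinals < 0) || any(ordinals >= nSamples))
    stop("ordinals must lie in [0, nSamples)")
  withSeed(seed, {
    ts <- vapply(clocks, function(cl) {
      base <- switch(mode,
        PULSED = ordinals / masterRate,
        ordinals / (cl@nominalRate * (1 + cl@driftPpm * 1e-6)))
      jit <- if (cl@jitterS > 0) stats::rnorm(length(ordinals), 0, cl@jitterS) else 0
      base + cl@latchDelayS + jit
    }, numeric(length(ordinals)))
    ts <- matrix(ts, nrow = length(ordinals),
                 dimnames = list(format(ordinals, scientific = FALSE), NULL))
    ts
  })
}

#' Maximum pairwise skew per sample ordinal
#'
#' Exact max-minus-min across modules at each ordinal of a
#' [simulateTimestamps()] matrix.
#'
#' @param timestamps matrix, ordinals x modules.
#' @return numeric vector of skews (seconds), one per ordinal.
#' @export
maxSkew <- function(timestamps) {
  if (ncol(timestamps) == 1L) return(rep(0, nrow(timestamps)))
  unname(apply(timestamps, 1L, max) - apply(timestamps, 1L, min))
}

#' Merge per-module sessions into a combined dataset
#'
#' Reconstructs a multi-module recording: rows are keyed by unwrapped
#' sample index, columns are the concatenated channels in module-major
#' order (module 1's 1024 neural + 96 aux channels, then module 2's, ...).
#' All sessions must share an experiment id and carry pairwise distinct
#' module ids. A sample missing from any module yields `NA` in that
#' module's columns and a row in the gap report — never a silent
#' misalignment.
#'
#' @param sessions list of [ModuleSession-class] objects or session file
#'   paths.
#' @param layout a [RecordLayout-class] (for file inputs).
#' @return a [SummarizedExperiment::SummarizedExperiment-class]: assay
#'   `"adc"` is channels x unwrapped-index, `rowData` holds `module`
#'   (1-based position), `moduleId`, `channelId` and `type`; `colData`
#'   holds `unwrappedIndex`; `metadata` holds `experimentId`, `moduleIds`
#'   and `gaps` (data.frame of `module`, `unwrappedIndex`).
#' @examples
#' a <- moduleSession(experimentId = 9, moduleId = 1, n = 3)
#' b <- moduleSession(experimentId = 9, moduleId = 2, n = 3)
#' dim(mergeSessions(list(a, b)))  # 2240 x 3
#' @export
mergeSessions <- function(sessions, layout = recordLayout()) {
  if (length(sessions) == 0) stop("need at least one session")
  sessions <- lapply(sessions, function(s)
    if (is.character(s)) readSession(s, layout) else s)
  expIds <- vapply(sessions, experimentId, numeric(1))
  modIds <- vapply(sessions, moduleId, numeric(1))
  if (length(unique(expIds)) != 1L)
    stop("sessions mix acquisition sessions: experiment ids ",
         paste(format(unique(expIds), scientific = FALSE), collapse = ", "))
  if (anyDuplicated(modIds))
    stop("duplicate module id: ",
         format(modIds[duplicated(modIds)][1], scientific = FALSE))
  unwrapped <- lapply(sessions, function(s) unwrapIndices(sampleIndex(s)))
  allIdx <- sort(unique(unlist(unwrapped)))
  lay <- sessions[[1]]@layout
  nn <- nNeuralChannels(lay)
  na <- nAuxChannels(lay)
  perMod <- nn + na
  m <- length(sessions)
  data <- matrix(NA_integer_, perMod * m, length(allIdx))
  gaps <- list()
  for (j in seq_len(m)) {
    col <- match(unwrapped[[j]], allIdx)
    rows <- (j - 1L) * perMod
    data[rows + seq_len(nn), col] <- neuralData(sessions[[j]])
    data[rows + nn + seq_len(na), col] <- auxData(sessions[[j]])
    miss <- setdiff(allIdx, unwrapped[[j]])
    if (length(miss))
      gaps[[length(gaps) + 1L]] <- data.frame(module = j, unwrappedIndex = miss)
  }
  gaps <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(module = numeric(0), unwrappedIndex = numeric(0))
  rowData <- S4Vectors::DataFrame(
    module = rep(seq_len(m), each = perMod),
    moduleId = rep(modIds, each = perMod),
    channelId = rep(c(seq_len(nn), nn + seq_len(na)) - 1L, m),
    type = rep(rep(c("neural", "aux"), c(nn, na)), m))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(adc = data), rowData = rowData,
    colData = S4Vectors::DataFrame(unwrappedIndex = allIdx),
    metadata = list(experimentId = expIds[1], moduleIds = modIds,
                    gaps = gaps))
}

#' Write a merged dataset as a flat binary container
#'
#' Stores a [mergeSessions()] result as channel-major flat 16-bit
#' little-endian binary (`<prefix>.i16`, one channel's full time series
#' after another; gaps encoded as 0xFFFF with their positions in the
#' sidecar) plus a JSON metadata sidecar (`<prefix>.json`).
#'
#' @param merged a `SummarizedExperiment` from [mergeSessions()].
#' @param prefix output path prefix.
#' @return invisibly, the two paths written.
#' @export
writeMerged <- function(merged, prefix) {
  data <- SummarizedExperiment::assay(merged, "adc")
  filled <- data
  filled[is.na(filled)] <- 65535L
  binPath <- paste0(prefix, ".i16")
  con <- file(binPath, "wb")
  writeBin(wordsToRaw(t(filled)), con)  # channel-major: each row contiguous
  close(con)
  meta <- S4Vectors::metadata(merged)
  jsonPath <- paste0(prefix, ".json")
  jsonlite::write_json(list(
    experiment_id = meta$experimentId,
    module_ids = meta$moduleIds,
    n_channels = nrow(data), n_samples = ncol(data),
    unwrapped_index_first = if (ncol(data)) SummarizedExperiment::colData(merged)$unwrappedIndex[1] else NA,
    gap_fill_code = 65535,
    gaps = meta$gaps,
    layout = "channel-major flat u16 little-endian"),
    jsonPath, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(binPath, jsonPath))
}
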