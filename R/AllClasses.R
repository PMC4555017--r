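#' @import methods
NULL

#' Byte-level layout of the on-disk record format
#'
#' A `RecordLayout` collects the constants every codec and budget operation
#' derives from: the 20-byte per-sample metadata header, 2048 bytes of neural
#' data (32 chips x 32 channels x 16 bit), 192 bytes of auxiliary data
#' (3 channels per chip), zero padding to a fixed 4096-byte record, and the
#' 128-sample write block. The default layout gives the canonical
#' 122.88 MB/s aggregate rate at 30 kS/s.
#'
#' @slot metaBytes,neuralBytes,auxBytes,padBytes,recordBytes section sizes in
#'   bytes; the four sections must sum to `recordBytes` for a physically
#'   writable layout (checked by [recordLayout()], not by the class, so that
#'   hypothetical layouts can be used in budget what-if arithmetic).
#' @slot blockSamples,blockBytes write-block granularity.
#' @slot sampleRate neural sample rate in samples/s.
#' @slot nChips,channelsPerChip,auxPerChip amplifier chip geometry.
#' @slot nGpio,gpioRate GPIO line count and state sample rate (Hz).
#'
#' @seealso [recordLayout()], [dataRate()], [encodeSample()]
#' @export
setClass("RecordLayout", representation(
  metaBytes = "numeric", neuralBytes = "numeric", auxBytes = "numeric",
  padBytes = "numeric", recordBytes = "numeric",
  blockSamples = "numeric", blockBytes = "numeric",
  sampleRate = "numeric",
  nChips = "numeric", channelsPerChip = "numeric", auxPerChip = "numeric",
  nGpio = "numeric", gpioRate = "numeric"))

setValidity("RecordLayout", function(object) {
  v <- c(object@metaBytes, object@neuralBytes, object@auxBytes,
         object@padBytes, object@recordBytes, object@blockSamples,
         object@blockBytes, object@sampleRate, object@nChips,
         object@channelsPerChip, object@auxPerChip, object@nGpio,
         object@gpioRate)
  if (any(!is.finite(v)) || any(v < 0)) return("layout fields must be finite and non-negative")
  if (object@blockBytes != object@blockSamples * object@recordBytes)
    return("blockBytes must equal blockSamples * recordBytes")
  TRUE
})

#' An in-memory session of complete module samples
#'
#' One time point of a module's output (a "complete module sample") is 20
#' bytes of metadata, 1024 neural words and 96 auxiliary words. A
#' `ModuleSession` holds an ordered run of such samples column-wise:
#' channels are rows (chip-major: chip 0 channels 0-31, then chip 1, ...),
#' samples are columns, values are raw unsigned 16-bit ADC codes.
#'
#' @slot experimentId session tag shared by all data of one acquisition
#'   session; by convention a 64-bit UNIX UTC timestamp (held as a double,
#'   exact below 2^53).
#' @slot moduleId 32-bit module identity (bottom 32 bits of a MAC address).
#' @slot sampleIndex per-sample 32-bit sequence counter; wraps modulo 2^32.
#' @slot chipLive per-sample 32-bit mask, bit i set iff chip i is active.
#'   Channels of inactive chips carry filler and must be ignored.
#' @slot neural integer matrix, `neuralChannels x n` (1024 rows by default).
#' @slot aux integer matrix, `auxChannels x n` (96 rows by default).
#' @slot layout the [RecordLayout-class] the session encodes under.
#'
#' @seealso [moduleSession()], [encodeSample()], [writeSession()]
#' @export
setClass("ModuleSession", representation(
  experimentId = "numeric", moduleId = "numeric",
  sampleIndex = "numeric", chipLive = "numeric",
  neural = "matrix", aux = "matrix",
  layout = "RecordLayout"))

setValidity("ModuleSession", function(object) {
  n <- length(object@sampleIndex)
  lay <- object@layout
  if (length(object@experimentId) != 1L || length(object@moduleId) != 1L)
    return("experimentId and moduleId must be scalars")
  if (object@experimentId < 0 || object@experimentId >= 2^53)
    return("experimentId out of representable range")
  if (object@moduleId < 0 || object@moduleId >= 2^32)
    return("moduleId must be an unsigned 32-bit value")
  if (length(object@chipLive) != n) return("chipLive length must match sampleIndex")
  if (any(object@sampleIndex < 0) || any(object@sampleIndex >= 2^32))
    return("sampleIndex values must be unsigned 32-bit")
  if (any(object@chipLive < 0) || any(object@chipLive >= 2^32))
    return("chipLive values must be unsigned 32-bit")
  if (ncol(object@neural) != n || ncol(object@aux) != n)
    return("neural/aux column count must match sample count")
  if (nrow(object@neural) != lay@neuralBytes / 2)
    return("neural row count must match layout")
  if (nrow(object@aux) != lay@auxBytes / 2)
    return("aux row count must match layout")
  if (n > 0L) {
    rng <- range(object@neural, object@aux)
    if (rng[1] < 0 || rng[2] > 65535) return("channel values must fit in 16 bits")
  }
  TRUE
})

#' Generative model parameters for synthetic sessions
#'
#' Configuration of the acquisition-front-end emulator: Poisson-spiking
#' units rendered onto a close-packed electrode array over a white Gaussian
#' noise floor, quantized to unsigned 16-bit ADC codes, with GPIO state
#' sampled at 2 kHz embedded in a designated auxiliary channel.
#'
#' @slot nChips number of amplifier chips populated (1..32).
#' @slot deadChips integer chip ids (0-based) whose live bit is cleared;
#'   their channels carry zero filler.
#' @slot sampleRate samples/s (30000 by default).
#' @slot durationSamples session length in samples.
#' @slot noiseRmsUv input-referred noise floor, microvolt RMS.
#' @slot lsbUv microvolts per ADC code (mid-scale code 32768 is 0 uV).
#' @slot nUnits,firingRateHz number of simulated units and per-unit
#'   homogeneous Poisson rate.
#' @slot waveform spike template in microvolts at the soma (about 1 ms,
#'   biphasic; the vector's extremum is the peak amplitude).
#' @slot geometry site positions in micrometers, `nSites x 2`, mapped to
#'   neural channels row-by-row.
#' @slot unitPositions `nUnits x 2` positions; `NA` means draw uniformly
#'   over the array footprint from the seed.
#' @slot spatialDecayUm exponential length constant of amplitude falloff
#'   with site distance.
#' @slot gpioPattern a 16-bit constant, or a function of time (s) returning
#'   a 16-bit word, evaluated on the 2 kHz GPIO tick grid.
#' @slot gpioAuxChannel global aux slot (0-based, 0..95) that carries the
#'   GPIO word.
#' @slot startIndex initial 32-bit sample index (rollover at 2^32).
#' @slot experimentId,moduleId session metadata constants.
#' @slot seed RNG seed; generation is a pure function of (config, seed).
#'
#' @seealso [simConfig()], [generateSession()]
#' @export
setClass("SimConfig", representation(
  nChips = "numeric", deadChips = "numeric", sampleRate = "numeric",
  durationSamples = "numeric", noiseRmsUv = "numeric", lsbUv = "numeric",
  nUnits = "numeric", firingRateHz = "numeric", waveform = "numeric",
  geometry = "matrix", unitPositions = "matrix", spatialDecayUm = "numeric",
  gpioPattern = "ANY", gpioAuxChannel = "numeric",
  startIndex = "numeric", experimentId = "numeric", moduleId = "numeric",
  seed = "numeric"))

setValidity("SimConfig", function(object) {
  if (object@nChips < 1 || object@nChips > 32) return("nChips must be in 1..32")
  if (object@durationSamples < 1) return("durationSamples must be >= 1")
  if (object@noiseRmsUv < 0) return("noiseRmsUv must be >= 0")
  if (object@firingRateHz < 0) return("firingRateHz must be >= 0")
  if (object@lsbUv <= 0) return("lsbUv must be > 0")
  if (length(object@deadChips) && (any(object@deadChips < 0) || any(object@deadChips >= 32)))
    return("deadChips must be chip ids 0..31")
  if (object@gpioAuxChannel < 0 || object@gpioAuxChannel > 95)
    return("gpioAuxChannel must be a global aux slot 0..95")
  if (object@startIndex < 0 || object@startIndex >= 2^32)
    return("startIndex must be unsigned 32-bit")
  if (!is.function(object@gpioPattern) && !is.numeric(object@gpioPattern))
    return("gpioPattern must be a 16-bit constant or a function of time")
  TRUE
})

#' Outcome of a session integrity check
#'
#' Structured result of [validateSession()]: summary counters plus a full
#' census of error events, each tagged with its kind and the 0-based record
#' ordinal where it was observed.
#'
#' Error kinds: `ID_CHANGE` (experiment/module id or chip-live mask changed
#' mid-session), `INDEX_SKIP` (sample counter advanced by 2 or more, modulo
#' 2^32), `INDEX_REPEAT` (counter did not advance), `NONZERO_PADDING`,
#' `TRUNCATED_TAIL` (trailing remainder shorter than one record),
#' `SIZE_MISMATCH` (record count disagrees with the expected byte count).
#'
#' @slot nRecords number of whole 4096-byte records.
#' @slot bytes,remainderBytes total bytes scanned and trailing remainder.
#' @slot firstIndexRaw,lastIndexRaw raw 32-bit counters at the ends.
#' @slot firstIndexUnwrapped,lastIndexUnwrapped 64-bit unwrapped counters.
#' @slot experimentId,moduleId the constants observed in record 0.
#' @slot errors data.frame with columns `kind`, `recordOrdinal`, `detail`.
#' @slot passed `TRUE` iff `errors` is empty.
#'
#' @seealso [validateSession()], [summarizeReport()]
#' @export
setClass("ValidationReport", representation(
  nRecords = "numeric", bytes = "numeric", remainderBytes = "numeric",
  firstIndexRaw = "numeric", lastIndexRaw = "numeric",
  firstIndexUnwrapped = "numeric", lastIndexUnwrapped = "numeric",
  experimentId = "numeric", moduleId = "numeric",
  errors = "data.frame", passed = "logical"))

setValidity("ValidationReport", function(object) {
  if (!identical(object@passed, nrow(object@errors) == 0L))
    return("passed must be TRUE exactly when the error census is empty")
  if (!all(c("kind", "recordOrdinal", "detail") %in% names(object@errors)))
    return("errors must have kind/recordOrdinal/detail columns")
  TRUE
})

#' A module's sampling clock for synchronization simulation
#'
#' @slot nominalRate nominal sample rate, samples/s.
#' @slot driftPpm frequency error in parts per million (|drift| < 1000).
#' @slot jitterS per-edge timing noise standard deviation, seconds.
#' @slot latchDelayS fixed pulse-to-sample latch latency, seconds.
#'
#' @seealso [moduleClock()], [simulateTimestamps()]
#' @export
setClass("ModuleClock", representation(
  nominalRate = "numeric", driftPpm = "numeric",
  jitterS = "numeric", latchDelayS = "numeric"))

setValidity("ModuleClock", function(object) {
  if (abs(object@driftPpm) >= 1000) return("|driftPpm| must be < 1000")
  if (object@jitterS < 0) return("jitterS must be >= 0")
  if (object@nominalRate <= 0) return("nominalRate must be > 0")
  TRUE
})
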