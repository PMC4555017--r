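#' Construct a record layout
#'
#' Builds a [RecordLayout-class] from the chip geometry and record size.
#' Section sizes are derived: `neuralBytes = 2 * nChips * channelsPerChip`,
#' `auxBytes = 2 * nChips * auxPerChip`, and the zero padding is whatever
#' remains up to `recordBytes`. The defaults reproduce the canonical format:
#' 20 + 2048 + 192 + 1836 = 4096 bytes per sample, 128-sample write blocks,
#' and an aggregate rate of 4096 x 30000 = 122.88 MB/s.
#'
#' Each record is padded to a fixed size so that every sample occupies the
#' same number of bytes on disk; the stream then needs no file system,
#' headers or separators, and the k-th sample starts at byte `k * 4096`.
#'
#' @param nChips,channelsPerChip,auxPerChip amplifier geometry (32 chips of
#'   32 neural + 3 auxiliary channels by default).
#' @param sampleRate samples per second (30000).
#' @param recordBytes on-disk bytes per sample (4096).
#' @param metaBytes metadata header size (20).
#' @param blockSamples samples per write block (128).
#' @param nGpio,gpioRate GPIO line count and state rate in Hz.
#' @return a validated [RecordLayout-class] object.
#' @examples
#' lay <- recordLayout()
#' dataRate(lay)         # 122880000 bytes/s
#' totalChannelCount(lay)  # 1120
#' @export
recordLayout <- function(nChips = 32, channelsPerChip = 32, auxPerChip = 3,
                         sampleRate = 30000, recordBytes = 4096,
                         metaBytes = 20, blockSamples = 128,
                         nGpio = 16, gpioRate = 2000) {
  neuralBytes <- 2 * nChips * channelsPerChip
  auxBytes <- 2 * nChips * auxPerChip
  padBytes <- recordBytes - metaBytes - neuralBytes - auxBytes
  if (padBytes < 0)
    stop("sections exceed recordBytes: need ", metaBytes + neuralBytes + auxBytes,
         " bytes but recordBytes is ", recordBytes)
  new("RecordLayout",
      metaBytes = metaBytes, neuralBytes = neuralBytes, auxBytes = auxBytes,
      padBytes = padBytes, recordBytes = recordBytes,
      blockSamples = blockSamples, blockBytes = blockSamples * recordBytes,
      sampleRate = sampleRate,
      nChips = nChips, channelsPerChip = channelsPerChip,
      auxPerChip = auxPerChip, nGpio = nGpio, gpioRate = gpioRate)
}

nNeuralChannels <- function(layout) layout@neuralBytes / 2
nAuxChannels <- function(layout) layout@auxBytes / 2

setMethod("show", "RecordLayout", function(object) {
  cat("RecordLayout:", object@recordBytes, "B/record =",
      object@metaBytes, "meta +", object@neuralBytes, "neural +",
      object@auxBytes, "aux +", object@padBytes, "pad\n")
  cat("  ", nNeuralChannels(object), "neural +", nAuxChannels(object),
      "aux channels @", object@sampleRate, "S/s;",
      object@blockSamples, "-sample blocks (", object@blockBytes, "B)\n")
})

#' @describeIn ModuleSession-accessors the layout a session encodes under.
#' @export
setMethod("layoutOf", "ModuleSession", function(x) x@layout)
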