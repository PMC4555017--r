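# Closed-form rate, overhead, capacity and headroom arithmetic. Decimal
# storage units throughout: 1 MB = 10^6 bytes, 1 GB = 10^9 bytes — the only
# convention under which 4096 bytes x 30000 samples/s prints as 122.88 MB/s.

#' System budget arithmetic
#'
#' Closed-form figures of merit for a record layout: aggregate and payload
#' data rates, metadata and padding overheads, drive capacity, counter
#' rollover horizon, per-chip link rate, channel counts, the padding-budget
#' headroom in extra neural channels, and SATA headroom.
#'
#' Two overheads quote different denominators by design: the metadata
#' overhead is relative to the 2240-byte channel payload
#' (20 / 2240 = 0.9%), while the padding fraction is relative to the full
#' 4096-byte record (1836 / 4096 = 44.8%) — these are the denominators that
#' reproduce both printed figures.
#'
#' @param layout a [RecordLayout-class].
#' @param driveBytes drive capacity in bytes (decimal; 512 GB = 512e9).
#' @param sataLimit interface payload rate in bytes/s; SATA 1 is
#'   187,500,000 B/s.
#' @return `dataRate()`, `channelDataRate()`: bytes/s.
#'   `metadataOverheadPct()`, `paddingPct()`: percent, rounded to 1 decimal.
#'   `recordingCapacity()`: list with `samples`, `seconds`, `minutesCeil`
#'   (whole minutes, rounded up to match the usual "up to N min" phrasing).
#'   `rolloverHours()`: whole hours (floor) until the 32-bit counter wraps.
#'   `perChipRateMbit()`: Mbit/s on one amplifier chip's serial link.
#'   `totalChannelCount()`: neural + auxiliary channels.
#'   `extraChannelCapacity()`: how many additional neural channels (with
#'   proportional aux channels and metadata) the padding budget could carry.
#'   `sataHeadroom()`: list with `fits` and `margin` (bytes/s).
#' @examples
#' lay <- recordLayout()
#' dataRate(lay) / 1e6             # 122.88 MB/s
#' recordingCapacity(lay, 512e9)$minutesCeil   # 70
#' metadataOverheadPct(lay)        # 0.9
#' paddingPct(lay)                 # 44.8
#' extraChannelCapacity(lay)       # 831
#' @name budget
NULL

#' @rdname budget
#' @export
dataRate <- function(layout = recordLayout()) {
  layout@recordBytes * layout@sampleRate
}

#' @rdname budget
#' @export
channelDataRate <- function(layout = recordLayout()) {
  (layout@neuralBytes + layout@auxBytes) * layout@sampleRate
}

#' @rdname budget
#' @export
metadataOverheadPct <- function(layout = recordLayout()) {
  payload <- layout@neuralBytes + layout@auxBytes
  if (payload == 0) return(if (layout@metaBytes == 0) 0 else Inf)
  round(100 * layout@metaBytes / payload, 1)
}

#' @rdname budget
#' @export
paddingPct <- function(layout = recordLayout()) {
  if (layout@recordBytes == 0) return(0)
  round(100 * layout@padBytes / layout@recordBytes, 1)
}

#' @rdname budget
#' @export
recordingCapacity <- function(layout = recordLayout(), driveBytes) {
  if (driveBytes <= 0) stop("driveBytes must be > 0")
  samples <- driveBytes %/% layout@recordBytes
  seconds <- samples / layout@sampleRate
  list(samples = samples, seconds = seconds,
       minutesCeil = ceiling(seconds / 60))
}

#' @rdname budget
#' @export
rolloverHours <- function(layout = recordLayout()) {
  floor(2^32 / layout@sampleRate / 3600)
}

#' @rdname budget
#' @export
perChipRateMbit <- function(layout = recordLayout()) {
  (layout@channelsPerChip + layout@auxPerChip) * layout@sampleRate * 16 / 1e6
}

#' @rdname budget
#' @export
totalChannelCount <- function(layout = recordLayout()) {
  layout@nChips * (layout@channelsPerChip + layout@auxPerChip)
}

#' @rdname budget
#' @export
extraChannelCapacity <- function(layout = recordLayout()) {
  nn <- nNeuralChannels(layout)
  if (nn == 0) return(0)
  # marginal cost of one neural channel: its own 2 bytes, plus aux and
  # metadata scaled in proportion to the existing aux/neural and
  # meta/neural ratios (continuous accounting; whole-chip granularity
  # cannot reproduce the published headroom)
  costPerChannel <- 2 + layout@auxBytes / nn + layout@metaBytes / nn
  floor(layout@padBytes / costPerChannel)
}

#' @rdname budget
#' @export
sataHeadroom <- function(layout = recordLayout(), sataLimit = 187500000) {
  rate <- dataRate(layout)
  list(fits = rate <= sataLimit, margin = sataLimit - rate)
}

#' All budget figures as one table
#'
#' Convenience summary used by the command-line `budget` subcommand.
#'
#' @inheritParams budget
#' @return a data.frame with `figure`, `value`, `unit` columns.
#' @export
budgetTable <- function(layout = recordLayout(), driveBytes = 512e9) {
  cap <- recordingCapacity(layout, driveBytes)
  head <- sataHeadroom(layout)
  data.frame(
    figure = c("total_data_rate", "channel_data_rate", "metadata_overhead",
               "padding_fraction", "per_chip_rate", "total_channels",
               "neural_bytes_per_sample", "record_bytes", "block_bytes",
               "rollover_horizon", "drive_capacity_samples",
               "drive_capacity_minutes", "extra_channel_headroom",
               "sata1_margin"),
    value = c(dataRate(layout) / 1e6, channelDataRate(layout) / 1e6,
              metadataOverheadPct(layout), paddingPct(layout),
              perChipRateMbit(layout), totalChannelCount(layout),
              layout@neuralBytes, layout@recordBytes, layout@blockBytes,
              rolloverHours(layout), cap$samples, cap$minutesCeil,
              extraChannelCapacity(layout), head$margin / 1e6),
    unit = c("MB/s", "MB/s", "% of channel rate", "% of record", "Mbit/s",
             "channels", "bytes", "bytes", "bytes", "hours", "samples",
             "min", "neural channels", "MB/s"))
}
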