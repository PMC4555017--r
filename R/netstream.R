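# Software model of the Ethernet data plane. The acquisition module
# distributes a copy of the neural data as UDP datagrams: either snapshots
# of all 1024 channels of one sample, or a continuous stream of selected
# channels. UDP gives no delivery guarantee, so the receiver must tolerate
# loss, reordering and duplication, and report gaps instead of blocking —
# the complete record always lives on the drive, not on the network.
#
# The paper does not define a payload layout, so this is the package's own
# wire dialect (version 1), little-endian:
#
#   offset 0   4 B  magic "NDQ1"
#   offset 4   1 B  mode (0 = SNAPSHOT, 1 = STREAM)
#   offset 5   1 B  reserved (0)
#   offset 6   2 B  channel_start (u16)  - first channel of this fragment:
#                   absolute id for snapshots, offset into the subscribed
#                   channel list for streams
#   offset 8   2 B  channel_count (u16)
#   offset 10  2 B  fragment_ordinal (u16)
#   offset 12  2 B  fragment_total (u16)
#   offset 14  8 B  experiment_id (u64)
#   offset 22  4 B  module_id (u32)
#   offset 26  4 B  sample_index (u32)
#   offset 30  2*channel_count B  payload words
#
# The 30-byte header plus a default cap of 720 payload words keeps every
# serialized packet at or under 1470 bytes — inside the 1472-byte payload
# of a standard Ethernet frame after UDP/IP headers.

PACKET_HEADER_BYTES <- 30L
PACKET_MAGIC <- charToRaw("NDQ1")
MAX_PAYLOAD_WORDS <- 720L

newPacket <- function(mode, experimentId, moduleId, sampleIndex,
                      channelStart, fragmentOrdinal, fragmentTotal, payload) {
  list(mode = mode, experimentId = as.numeric(experimentId),
       moduleId = as.numeric(moduleId), sampleIndex = as.numeric(sampleIndex),
       channelStart = as.integer(channelStart),
       channelCount = length(payload),
       fragmentOrdinal = as.integer(fragmentOrdinal),
       fragmentTotal = as.integer(fragmentTotal),
       payload = as.integer(payload))
}

#' Packetize one full-array snapshot
#'
#' Fragments one complete 1024-channel sample across the minimum number of
#' datagrams respecting the frame-size cap; all fragments carry the
#' sample's index so the receiver can reassociate them.
#'
#' @param sample a one-sample [ModuleSession-class].
#' @param maxWords payload cap per packet, in 16-bit words (720 by default,
#'   the largest cap fitting a standard Ethernet frame).
#' @return list of packets (see [serializePacket()] for the wire form).
#' @examples
#' s <- moduleSession(n = 1)
#' length(packetizeSnapshot(s, maxWords = 700))  # 2 fragments: 700 + 324
#' @export
packetizeSnapshot <- function(sample, maxWords = MAX_PAYLOAD_WORDS) {
  if (nSamples(sample) != 1L) stop("a snapshot is a single sample")
  if (maxWords < 1) stop("maxWords must be >= 1")
  vec <- as.integer(sample@neural[, 1])
  nFrag <- ceiling(length(vec) / maxWords)
  lapply(seq_len(nFrag), function(i) {
    lo <- (i - 1L) * maxWords + 1L
    hi <- min(i * maxWords, length(vec))
    newPacket(mode = "SNAPSHOT", experimentId = sample@experimentId,
              moduleId = sample@moduleId,
              sampleIndex = sample@sampleIndex[1],
              channelStart = lo - 1L, fragmentOrdinal = i - 1L,
              fragmentTotal = nFrag, payload = vec[lo:hi])
  })
}

#' Packetize a continuous stream of selected channels
#'
#' One packet per sample per channel batch (batches of at most `maxWords`
#' subscribed channels), ordered by sample index. `channelStart` addresses
#' the subscribed channel list, which receiver and sender share out of
#' band via the control plane.
#'
#' @param session a [ModuleSession-class].
#' @param channelIds 0-based neural/aux channel ids to stream (0..1119).
#' @param maxWords payload cap per packet in words.
#' @return list of packets.
#' @export
packetizeStream <- function(session, channelIds, maxWords = MAX_PAYLOAD_WORDS) {
  if (length(channelIds) == 0) stop("channel selection must be non-empty")
  lay <- session@layout
  nn <- nNeuralChannels(lay)
  if (any(channelIds < 0) || any(channelIds >= nn + nAuxChannels(lay)))
    stop("channel ids must be in 0..", nn + nAuxChannels(lay) - 1)
  isNeural <- channelIds < nn
  vals <- matrix(0L, length(channelIds), nSamples(session))
  vals[isNeural, ] <- session@neural[channelIds[isNeural] + 1L, , drop = FALSE]
  vals[!isNeural, ] <- session@aux[channelIds[!isNeural] - nn + 1L, , drop = FALSE]
  nFrag <- ceiling(length(channelIds) / maxWords)
  out <- vector("list", nSamples(session) * nFrag)
  k <- 0L
  for (s in seq_len(nSamples(session))) {
    for (i in seq_len(nFrag)) {
      lo <- (i - 1L) * maxWords + 1L
      hi <- min(i * maxWords, length(channelIds))
      k <- k + 1L
      out[[k]] <- newPacket(mode = "STREAM",
                            experimentId = session@experimentId,
                            moduleId = session@moduleId,
                            sampleIndex = session@sampleIndex[s],
                            channelStart = lo - 1L, fragmentOrdinal = i - 1L,
                            fragmentTotal = nFrag, payload = vals[lo:hi, s])
    }
  }
  out
}

#' Simulate an unreliable datagram channel
#'
#' Drops each packet independently with probability `lossProb` (Bernoulli),
#' the failure mode UDP exposes: no retransmission, no delivery guarantee.
#' Deterministic per seed.
#'
#' @param packets list of packets.
#' @param lossProb per-packet drop probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return the surviving packets, in order.
#' @export
lossyChannel <- function(packets, lossProb, seed = 0) {
  if (lossProb < 0 || lossProb > 1) stop("lossProb must be in [0, 1]")
  keep <- withSeed(seed, stats::runif(length(packets)) >= lossProb)
  packets[keep]
}

#' Reassemble received packets
#'
#' Receiver-side reconstruction under UDP semantics: tolerant of
#' reordering and duplication, never blocking on loss. Snapshot fragments
#' are reassociated per sample index; streams are laid out as a channel x
#' sample matrix over the observed (or given) sample-index range. Every
#' missing fragment or sample is enumerated in the gap report.
#'
#' @param packets list of packets (any order; duplicates are idempotent).
#' @param expectedIndices optional vector of sample indices the receiver
#'   expected (e.g. from the control plane); defaults to the contiguous
#'   modular range spanned by the packets that did arrive.
#' @return list with `mode`, `data` (snapshots: channel x sample matrix of
#'   complete snapshots; streams: subscribed-channel x sample matrix with
#'   `NA` in gaps), `sampleIndices`, and `gapReport` (data.frame with
#'   `sampleIndex`, `fragmentOrdinal`; `NA` ordinal means the whole sample
#'   is missing).
#' @export
reassemble <- function(packets, expectedIndices = NULL) {
  if (length(packets) == 0)
    return(list(mode = NA_character_, data = NULL,
                sampleIndices = numeric(0),
                gapReport = data.frame(sampleIndex = numeric(0),
                                       fragmentOrdinal = numeric(0))))
  mode <- packets[[1]]$mode
  idx <- vapply(packets, `[[`, numeric(1), "sampleIndex")
  if (is.null(expectedIndices)) {
    # contiguous range spanned by what arrived; a receiver whose window
    # crosses an index rollover should pass expectedIndices explicitly
    expectedIndices <- seq(min(idx), max(idx))
  }
  nFrag <- packets[[1]]$fragmentTotal
  totalWords <- max(vapply(packets, function(p) p$channelStart + p$channelCount,
                           numeric(1)))
  data <- matrix(NA_integer_, totalWords, length(expectedIndices))
  seen <- matrix(FALSE, nFrag, length(expectedIndices))
  col <- match(idx, expectedIndices)
  for (i in seq_along(packets)) {
    p <- packets[[i]]
    if (is.na(col[i])) next  # outside the expected range
    if (seen[p$fragmentOrdinal + 1L, col[i]]) next  # duplicate
    seen[p$fragmentOrdinal + 1L, col[i]] <- TRUE
    data[p$channelStart + seq_len(p$channelCount), col[i]] <- p$payload
  }
  missing <- which(!seen, arr.ind = TRUE)
  wholeSample <- colSums(seen) == 0
  gapReport <- data.frame(
    sampleIndex = expectedIndices[missing[, "col"]],
    fragmentOrdinal = ifelse(wholeSample[missing[, "col"]],
                             NA_real_, missing[, "row"] - 1))
  gapReport <- unique(gapReport)  # a wholly missing sample is one row (NA ordinal)
  rownames(gapReport) <- NULL
  colnames(data) <- NULL
  list(mode = mode, data = data, sampleIndices = expectedIndices,
       gapReport = gapReport)
}

#' Serialize and parse datagrams
#'
#' `serializePacket()` renders a packet in the documented little-endian
#' wire layout; `parsePacket()` inverts it. `writePacketLog()` and
#' `readPacketLog()` store a packet sequence as a length-prefixed capture
#' file (u32 little-endian byte count before each datagram).
#'
#' @param packet a packet as produced by the packetizers.
#' @param bytes a raw vector holding one serialized packet.
#' @param packets list of packets.
#' @param path capture file path.
#' @return raw vector / packet / invisible path / list of packets.
#' @export
serializePacket <- function(packet) {
  stopifnotU16(packet$payload, "packet payload")
  modeByte <- if (packet$mode == "SNAPSHOT") 0L else 1L
  c(PACKET_MAGIC,
    as.raw(c(modeByte, 0L)),
    wordsToRaw(c(packet$channelStart, packet$channelCount,
                 packet$fragmentOrdinal, packet$fragmentTotal)),
    wordsToRaw(as.integer(u64ToWords(packet$experimentId))),
    wordsToRaw(as.integer(u32ToWords(packet$moduleId))),
    wordsToRaw(as.integer(u32ToWords(packet$sampleIndex))),
    wordsToRaw(packet$payload))
}

#' @rdname serializePacket
#' @export
parsePacket <- function(bytes) {
  if (length(bytes) < PACKET_HEADER_BYTES || !identical(bytes[1:4], PACKET_MAGIC))
    stop("not a version-1 data packet")
  w <- rawToWords(bytes[7:30])
  payload <- if (length(bytes) > 30) rawToWords(bytes[-(1:30)]) else integer(0)
  if (length(payload) != w[2]) stop("payload length disagrees with header")
  newPacket(mode = if (as.integer(bytes[5]) == 0L) "SNAPSHOT" else "STREAM",
            experimentId = wordsToU64(w[5], w[6], w[7], w[8]),
            moduleId = wordsToU32(w[9], w[10]),
            sampleIndex = wordsToU32(w[11], w[12]),
            channelStart = w[1], fragmentOrdinal = w[3], fragmentTotal = w[4],
            payload = payload)
}

#' @rdname serializePacket
#' @export
writePacketLog <- function(packets, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (p in packets) {
    b <- serializePacket(p)
    writeBin(wordsToRaw(as.integer(u32ToWords(length(b)))), con)
    writeBin(b, con)
  }
  invisible(path)
}

#' @rdname serializePacket
#' @export
readPacketLog <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  out <- list()
  repeat {
    lenRaw <- readBin(con, "raw", n = 4L)
    if (length(lenRaw) < 4L) break
    w <- rawToWords(lenRaw)
    out[[length(out) + 1L]] <- parsePacket(readBin(con, "raw",
                                                   n = wordsToU32(w[1], w[2])))
  }
  out
}

#' Network bandwidth of a channel selection
#'
#' Bits per second needed to stream `channelCount` channels at
#' `sampleRate`, including the per-packet header overhead at the chosen
#' fragmentation — used to check a selection against the 1 Gb/s link.
#'
#' @param channelCount number of streamed channels.
#' @param sampleRate samples per second.
#' @param maxWords payload cap per packet in words.
#' @param headerBytes per-packet header size.
#' @return list with `totalBitsPerS`, `payloadBitsPerS`, `headerBitsPerS`,
#'   `packetsPerS`, `fitsGigabit`.
#' @examples
#' streamBandwidth(1024)$payloadBitsPerS  # 491.52e6
#' @export
streamBandwidth <- function(channelCount, sampleRate = 30000,
                            maxWords = MAX_PAYLOAD_WORDS,
                            headerBytes = PACKET_HEADER_BYTES) {
  if (channelCount < 0) stop("channelCount must be >= 0")
  packetsPerSample <- ceiling(channelCount / maxWords)
  payload <- channelCount * 16 * sampleRate
  header <- packetsPerSample * headerBytes * 8 * sampleRate
  list(totalBitsPerS = payload + header, payloadBitsPerS = payload,
       headerBitsPerS = header, packetsPerS = packetsPerSample * sampleRate,
       fitsGigabit = (payload + header) <= 1e9)
}
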