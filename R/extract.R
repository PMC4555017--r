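# Channel extraction and export. Channels are numbered 0-based and
# chip-major: neural 0..1023 (chip i holds 32*i .. 32*i+31), auxiliary
# 1024..1119 (chip i holds 1024 + 3*i .. 1024 + 3*i + 2).

channelChip <- function(channelIds, layout) {
  nn <- nNeuralChannels(layout)
  ifelse(channelIds < nn,
         channelIds %/% layout@channelsPerChip,
         (channelIds - nn) %/% layout@auxPerChip)
}

#' Extract selected channels from a session
#'
#' Pulls the requested channels across all samples of a session file (read
#' in constant memory) or an in-memory [ModuleSession-class], and returns
#' them as a `SummarizedExperiment`: rows are the requested channels,
#' columns are samples ordered by unwrapped sample index.
#'
#' Channels belonging to chips whose chip-live bit is clear carry filler,
#' not signal; they are flagged `analyzable = FALSE` in the `rowData` (per
#' the format contract that inactive chips' data "should be ignored").
#'
#' @param x a session file path or a [ModuleSession-class].
#' @param channelIds 0-based channel ids; 0..1023 neural, 1024..1119 aux.
#' @param layout a [RecordLayout-class] (for file input).
#' @return a [SummarizedExperiment::SummarizedExperiment-class] with assay
#'   `"adc"` (unsigned 16-bit codes), `rowData` columns `channelId`, `chip`,
#'   `type`, `analyzable`, and `colData` column `unwrappedIndex`.
#' @examples
#' s <- moduleSession(experimentId = 7, n = 4,
#'                    neural = matrix(55L, 1024, 4))
#' se <- extractChannels(s, c(0, 1023, 1024))
#' SummarizedExperiment::assay(se)["ch1023", ]
#' @export
extractChannels <- function(x, channelIds, layout = recordLayout()) {
  nn <- nNeuralChannels(layout)
  na <- nAuxChannels(layout)
  total <- nn + na
  if (length(channelIds) == 0) stop("channelIds must be non-empty")
  if (any(channelIds < 0) || any(channelIds >= total))
    stop("channel ids must be in 0..", total - 1)
  isNeural <- channelIds < nn
  pick <- function(chunk) {
    vals <- matrix(0L, length(channelIds), nSamples(chunk))
    vals[isNeural, ] <- chunk@neural[channelIds[isNeural] + 1L, , drop = FALSE]
    vals[!isNeural, ] <- chunk@aux[channelIds[!isNeural] - nn + 1L, , drop = FALSE]
    vals
  }
  if (is.character(x)) {
    parts <- list(); idx <- list(); masks <- list()
    readSessionChunks(x, function(chunk, first) {
      parts[[length(parts) + 1L]] <<- pick(chunk)
      idx[[length(idx) + 1L]] <<- chunk@sampleIndex
      masks[[length(masks) + 1L]] <<- chunk@chipLive
      TRUE
    }, layout = layout)
    vals <- do.call(cbind, parts)
    rawIdx <- unlist(idx)
    mask <- unlist(masks)
  } else {
    layout <- x@layout
    vals <- pick(x)
    rawIdx <- x@sampleIndex
    mask <- x@chipLive
  }
  unwrapped <- unwrapIndices(rawIdx)
  chips <- channelChip(channelIds, layout)
  # chip i live in every sample <=> bit i of the mask always set
  liveAll <- vapply(chips, function(ch) all(mask %/% 2^ch %% 2 == 1), logical(1))
  rownames(vals) <- paste0("ch", channelIds)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(adc = vals),
    rowData = S4Vectors::DataFrame(
      channelId = channelIds, chip = chips,
      type = ifelse(isNeural, "neural", "aux"),
      analyzable = liveAll),
    colData = S4Vectors::DataFrame(unwrappedIndex = unwrapped))
}

#' Export extracted channels to portable files
#'
#' Writes each channel of an [extractChannels()] result as flat little-
#' endian 16-bit binary (`<prefix>_ch<k>.i16`) or as one delimited text
#' file (`<prefix>.csv`) with the unwrapped sample index as the first
#' column, plus a JSON sidecar (`<prefix>.json`) with the session metadata.
#'
#' @param se a `SummarizedExperiment` from [extractChannels()].
#' @param prefix output path prefix.
#' @param format `"csv"`, `"bin"`, or both.
#' @return invisibly, the paths written.
#' @export
exportChannels <- function(se, prefix, format = c("csv", "bin")) {
  format <- match.arg(format, several.ok = TRUE)
  vals <- SummarizedExperiment::assay(se, "adc")
  rd <- SummarizedExperiment::rowData(se)
  idx <- SummarizedExperiment::colData(se)$unwrappedIndex
  paths <- character(0)
  if ("csv" %in% format) {
    p <- paste0(prefix, ".csv")
    df <- data.frame(unwrapped_index = format(idx, scientific = FALSE, trim = TRUE),
                     t(vals), check.names = FALSE)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if ("bin" %in% format) {
    for (i in seq_len(nrow(vals))) {
      p <- paste0(prefix, "_ch", rd$channelId[i], ".i16")
      con <- file(p, "wb")
      writeBin(wordsToRaw(vals[i, ]), con)
      close(con)
      paths <- c(paths, p)
    }
  }
  sidecar <- paste0(prefix, ".json")
  jsonlite::write_json(list(
    channels = as.data.frame(rd),
    n_samples = ncol(vals),
    first_unwrapped_index = if (length(idx)) idx[1] else NA,
    format = format), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, sidecar))
}
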