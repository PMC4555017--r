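#' Construct an in-memory module session
#'
#' Assembles a [ModuleSession-class] from per-sample metadata and channel
#' matrices. A one-column session is a single "complete module sample".
#'
#' @param experimentId,moduleId session constants (64-bit UNIX timestamp and
#'   32-bit module identity by convention).
#' @param sampleIndex per-sample 32-bit counter; defaults to
#'   `startIndex, startIndex+1, ...` modulo 2^32.
#' @param chipLive per-sample 32-bit chip-live mask (recycled if scalar);
#'   defaults to all `nChips` low bits set.
#' @param neural,aux integer channel matrices, channels x samples, values
#'   0..65535. Scalars/vectors are recycled column-wise; missing sections
#'   default to zeros.
#' @param n number of samples when `neural` is not given.
#' @param startIndex first sample index when `sampleIndex` is not given.
#' @param layout a [RecordLayout-class].
#' @return a validated [ModuleSession-class].
#' @examples
#' s <- moduleSession(experimentId = 1443700000, moduleId = 0xdeadbe,
#'                    n = 3, startIndex = 10)
#' sampleIndex(s)
#' @export
moduleSession <- function(experimentId = 0, moduleId = 0,
                          sampleIndex = NULL, chipLive = NULL,
                          neural = NULL, aux = NULL,
                          n = if (is.null(neural)) 1L else ncol(neural),
                          startIndex = 0, layout = recordLayout()) {
  nn <- nNeuralChannels(layout)
  na <- nAuxChannels(layout)
  if (is.null(neural)) neural <- matrix(0L, nn, n)
  if (!is.matrix(neural)) neural <- matrix(as.integer(neural), nn, n)
  if (is.null(aux)) aux <- matrix(0L, na, ncol(neural))
  if (!is.matrix(aux)) aux <- matrix(as.integer(aux), na, ncol(neural))
  n <- ncol(neural)
  if (is.null(sampleIndex)) sampleIndex <- (startIndex + seq_len(n) - 1) %% 2^32
  if (is.null(chipLive)) chipLive <- 2^layout@nChips - 1
  chipLive <- rep_len(chipLive, n)
  storage.mode(neural) <- "integer"
  storage.mode(aux) <- "integer"
  new("ModuleSession", experimentId = experimentId, moduleId = moduleId,
      sampleIndex = as.numeric(sampleIndex), chipLive = as.numeric(chipLive),
      neural = neural, aux = aux, layout = layout)
}

#' Accessors for session objects
#'
#' @param x a [ModuleSession-class].
#' @name ModuleSession-accessors
#' @aliases nSamples sampleIndex chipLive neuralData auxData experimentId
#'   moduleId layoutOf
NULL

#' @describeIn ModuleSession-accessors number of samples (columns).
#' @export
setMethod("nSamples", "ModuleSession", function(x) length(x@sampleIndex))

#' @describeIn ModuleSession-accessors raw 32-bit sample counters.
#' @export
setMethod("sampleIndex", "ModuleSession", function(x) x@sampleIndex)

#' @describeIn ModuleSession-accessors per-sample chip-live masks.
#' @export
setMethod("chipLive", "ModuleSession", function(x) x@chipLive)

#' @describeIn ModuleSession-accessors neural channel matrix (channels x samples).
#' @export
setMethod("neuralData", "ModuleSession", function(x) x@neural)

#' @describeIn ModuleSession-accessors auxiliary channel matrix.
#' @export
setMethod("auxData", "ModuleSession", function(x) x@aux)

#' @describeIn ModuleSession-accessors session (experiment) identifier.
#' @export
setMethod("experimentId", "ModuleSession", function(x) x@experimentId)

#' @describeIn ModuleSession-accessors module identifier.
#' @export
setMethod("moduleId", "ModuleSession", function(x) x@moduleId)

#' @describeIn ModuleSession-accessors subset samples (columns) of a session.
#' @param i sample positions (1-based, as usual for R subsetting).
#' @param j,...,drop ignored.
#' @export
setMethod("[", "ModuleSession", function(x, i, j, ..., drop = FALSE) {
  initialize(x, sampleIndex = x@sampleIndex[i], chipLive = x@chipLive[i],
             neural = x@neural[, i, drop = FALSE],
             aux = x@aux[, i, drop = FALSE])
})

setMethod("show", "ModuleSession", function(object) {
  n <- nSamples(object)
  cat("ModuleSession:", n, "samples,",
      nrow(object@neural), "neural +", nrow(object@aux), "aux channels\n")
  cat("  experimentId:", format(object@experimentId, scientific = FALSE),
      " moduleId:", format(object@moduleId, scientific = FALSE), "\n")
  if (n > 0)
    cat("  sampleIndex:", format(object@sampleIndex[1], scientific = FALSE),
        "..", format(object@sampleIndex[n], scientific = FALSE),
        " chipLive: 0x", hex32(object@chipLive[1]), "\n",
        sep = "")
})

# shared consistency check for multi-chunk writes and merges
checkSameIdentity <- function(a, b) {
  if (a$experimentId != b$experimentId || a$moduleId != b$moduleId)
    stop("session identity changed mid-stream (experiment or module id)")
  invisible(TRUE)
}
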