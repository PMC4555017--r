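# Synthetic acquisition front end. Emulates what a module digitizes: a white
# Gaussian noise floor plus Poisson-spiking units rendered onto a
# close-packed site grid with exponential spatial falloff, quantized to
# unsigned 16-bit codes around mid-scale, with the 16 GPIO lines sampled at
# 2 kHz and held across 30 kS/s auxiliary slots. The generator is a pure
# function of (config, seed) and emits byte-identical sessions per seed.

SIM_CHUNK <- 4096L  # samples generated per internal chunk (fixed)

#' Default close-packed probe geometry
#'
#' Site positions for a close-packed silicon probe: `nColumns` columns at a
#' fixed pitch, filled row by row. The defaults (4 columns, 11.5 um pitch)
#' mirror a dense single-shank array whose neighbouring sites see the same
#' spike, so that a unit's footprint spans several recording sites.
#'
#' @param nSites number of recording sites (one per neural channel).
#' @param pitchUm center-to-center spacing in micrometers.
#' @param nColumns sites per row.
#' @return an `nSites x 2` matrix of x/y positions in micrometers.
#' @export
probeGeometry <- function(nSites = 1024, pitchUm = 11.5, nColumns = 4) {
  site <- seq_len(nSites) - 1L
  cbind(x = (site %% nColumns) * pitchUm,
        y = (site %/% nColumns) * pitchUm)
}

#' Default extracellular spike template
#'
#' A ~1 ms biphasic waveform: a sharp negative deflection followed by a
#' slower positive rebound, scaled so the extremum is `-peakUv` (negative
#' peak, as seen extracellularly near a soma).
#'
#' @param peakUv peak amplitude magnitude in microvolts.
#' @param sampleRate samples per second.
#' @param durationMs template length in milliseconds.
#' @return numeric vector of microvolt values.
#' @export
spikeTemplate <- function(peakUv = 150, sampleRate = 30000, durationMs = 1) {
  n <- max(8L, round(sampleRate * durationMs / 1000))
  t <- seq_len(n) - 1
  w <- -exp(-((t - 0.25 * n) / (0.08 * n))^2) +
    0.35 * exp(-((t - 0.6 * n) / (0.18 * n))^2)
  w / max(abs(w)) * peakUv  # extremum = -peakUv
}

#' Simulation configuration
#'
#' Builds a validated [SimConfig-class]. Defaults describe a fully
#' populated module (32 chips, 1024 neural channels) with the measured
#' 3.9 uV RMS system noise floor, a conventional amplifier scale of
#' 0.195 uV per ADC code, and a close-packed 4-column, 11.5 um-pitch site
#' grid. See [SimConfig-class] for field semantics.
#'
#' @param nChips,deadChips,sampleRate,durationSamples,noiseRmsUv,lsbUv,nUnits
#'   see [SimConfig-class].
#' @param firingRateHz,waveform,geometry,unitPositions,spatialDecayUm see
#'   [SimConfig-class].
#' @param gpioPattern,gpioAuxChannel,startIndex,experimentId,moduleId,seed
#'   see [SimConfig-class].
#' @return a [SimConfig-class].
#' @examples
#' cfg <- simConfig(nChips = 1, durationSamples = 3000, nUnits = 0, seed = 1)
#' s <- generateSession(cfg)
#' nSamples(s)
#' @export
simConfig <- function(nChips = 32, deadChips = numeric(0), sampleRate = 30000,
                      durationSamples = 30000, noiseRmsUv = 3.9,
                      lsbUv = 0.195, nUnits = 0, firingRateHz = 5,
                      waveform = spikeTemplate(), geometry = NULL,
                      unitPositions = NULL, spatialDecayUm = 25,
                      gpioPattern = 0, gpioAuxChannel = 0,
                      startIndex = 0, experimentId = 0, moduleId = 0,
                      seed = 0) {
  if (is.null(geometry)) geometry <- probeGeometry(nChips * 32)
  if (is.null(unitPositions)) unitPositions <- matrix(NA_real_, max(nUnits, 0), 2)
  new("SimConfig", nChips = nChips, deadChips = deadChips,
      sampleRate = sampleRate, durationSamples = durationSamples,
      noiseRmsUv = noiseRmsUv, lsbUv = lsbUv, nUnits = nUnits,
      firingRateHz = firingRateHz, waveform = waveform, geometry = geometry,
      unitPositions = unitPositions, spatialDecayUm = spatialDecayUm,
      gpioPattern = gpioPattern, gpioAuxChannel = gpioAuxChannel,
      startIndex = startIndex, experimentId = experimentId,
      moduleId = moduleId, seed = seed)
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields map directly onto [simConfig()] arguments; `gpioPattern`
#' must be a 16-bit constant in file form.
#'
#' @param path YAML file path.
#' @return a [SimConfig-class].
#' @export
simConfigFromYaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- intersect(names(vals), names(formals(simConfig)))
  if (!setequal(names(vals), known))
    stop("unknown config fields: ",
         paste(setdiff(names(vals), known), collapse = ", "))
  if (!is.null(vals$unitPositions))
    vals$unitPositions <- matrix(unlist(vals$unitPositions), ncol = 2, byrow = TRUE)
  do.call(simConfig, vals[known])
}

# internal: Poisson times on [0, duration), sorted; consumes the current RNG
poissonTimes <- function(rateHz, durationS) {
  n <- stats::rpois(1L, rateHz * durationS)
  sort(stats::runif(n, 0, durationS))
}

#' Homogeneous Poisson spike times
#'
#' @param rateHz firing rate in Hz.
#' @param durationS duration in seconds.
#' @param seed RNG seed; equal seeds give identical trains.
#' @return sorted numeric vector of event times in seconds.
#' @examples
#' length(generateSpikeTimes(10, 100, seed = 1))  # ~1000
#' @export
generateSpikeTimes <- function(rateHz, durationS, seed = 0) {
  if (rateHz < 0 || durationS < 0) stop("rate and duration must be >= 0")
  withSeed(seed, poissonTimes(rateHz, durationS))
}

#' Spatial amplitude footprint of a unit
#'
#' Amplitude seen at each recording site for a unit at `unitPosition`:
#' `peak * exp(-distance / decay)`. With a decay constant at or above the
#' inter-site pitch, several neighbouring sites exceed half the peak — the
#' close-packed footprint that makes such arrays spatially oversampling.
#'
#' @param geometry `nSites x 2` site positions (um).
#' @param unitPosition length-2 position of the unit (um).
#' @param peakUv peak amplitude (uV) at zero distance.
#' @param spatialDecayUm exponential length constant (um).
#' @return numeric vector of per-site amplitudes (uV).
#' @export
renderUnit <- function(geometry, unitPosition, peakUv, spatialDecayUm) {
  d <- sqrt((geometry[, 1] - unitPosition[1])^2 +
              (geometry[, 2] - unitPosition[2])^2)
  peakUv * exp(-d / spatialDecayUm)
}

#' Convert between microvolts and ADC codes
#'
#' The stream stores raw unsigned 16-bit codes; 0 uV sits at mid-scale code
#' 32768 and one LSB is `lsbUv` microvolts. `quantizeUv()` rounds and
#' saturates at the rails; `dequantizeCode()` is its (lossy) inverse.
#'
#' @param uv voltage(s) in microvolts.
#' @param code ADC code(s), 0..65535.
#' @param lsbUv microvolts per code.
#' @return codes (integer) or microvolts (numeric).
#' @examples
#' quantizeUv(0)        # 32768
#' quantizeUv(1e9)      # 65535 (saturated)
#' @export
quantizeUv <- function(uv, lsbUv = 0.195) {
  as.integer(pmin(pmax(round(uv / lsbUv) + 32768, 0), 65535))
}

#' @rdname quantizeUv
#' @export
dequantizeCode <- function(code, lsbUv = 0.195) {
  (code - 32768) * lsbUv
}

#' GPIO words on the neural sample grid
#'
#' The 16 GPIO lines are sampled at `gpioRate` (2 kHz) and their 16-bit
#' state is held for `sampleRate / gpioRate` (15) consecutive neural
#' samples, so that the GPIO stream embeds into one auxiliary channel slot
#' at the full 30 kS/s.
#'
#' @param durationSamples number of neural samples to cover.
#' @param pattern a 16-bit constant or `function(timeSeconds) -> word`,
#'   evaluated on the GPIO tick grid.
#' @param sampleRate,gpioRate neural and GPIO rates (Hz); their ratio must
#'   be a whole number of samples.
#' @param startSample 0-based global ordinal of the first sample.
#' @return integer vector of `durationSamples` 16-bit words.
#' @examples
#' gpioWords(30, 0xFFFF)
#' @export
gpioWords <- function(durationSamples, pattern, sampleRate = 30000,
                      gpioRate = 2000, startSample = 0) {
  hold <- sampleRate / gpioRate
  if (hold != floor(hold)) stop("sampleRate must be a multiple of gpioRate")
  k <- startSample + seq_len(durationSamples) - 1
  tick <- k %/% hold
  if (is.function(pattern)) {
    w <- vapply(unique(tick), function(tk) pattern(tk / gpioRate), numeric(1))
    out <- w[match(tick, unique(tick))]
  } else {
    out <- rep(pattern, durationSamples)
  }
  stopifnotU16(out, "GPIO words")
  as.integer(out)
}

# internal: everything deterministic that must be drawn before chunked
# noise generation (unit positions, then per-unit spike trains)
simPrepare <- function(config) {
  lay <- recordLayout()
  durS <- config@durationSamples / config@sampleRate
  pos <- config@unitPositions
  nLiveSites <- nrow(config@geometry)
  if (config@nUnits > 0 && anyNA(pos)) {
    lim <- apply(config@geometry, 2, range)
    pos <- cbind(stats::runif(config@nUnits, lim[1, 1], lim[2, 1]),
                 stats::runif(config@nUnits, lim[1, 2], lim[2, 2]))
  }
  spikes <- lapply(seq_len(config@nUnits), function(u)
    round(poissonTimes(config@firingRateHz, durS) * config@sampleRate))
  liveChips <- setdiff(seq_len(config@nChips) - 1L, config@deadChips)
  mask <- sum(2^liveChips)
  liveRows <- as.integer(outer(1:32, liveChips * 32L, `+`))
  peak <- config@waveform[which.max(abs(config@waveform))]
  amps <- lapply(seq_len(config@nUnits), function(u) {
    a <- renderUnit(config@geometry, pos[u, ], peak, config@spatialDecayUm)
    keep <- which(abs(a) >= abs(peak) * 1e-4 & seq_len(nLiveSites) %in% liveRows)
    list(sites = keep, amp = a[keep] / peak)
  })
  list(layout = lay, spikes = spikes, amps = amps, mask = mask,
       liveRows = liveRows, unitPositions = pos)
}

# internal: generate samples k0..k0+m-1 (0-based) as a ModuleSession chunk;
# consumes the RNG stream (noise) in chunk order
simChunk <- function(config, prep, k0, m) {
  lay <- prep$layout
  nn <- nNeuralChannels(lay)
  neural <- matrix(0L, nn, m)
  L <- length(config@waveform)
  if (length(prep$liveRows)) {
    uv <- matrix(stats::rnorm(length(prep$liveRows) * m, 0, config@noiseRmsUv),
                 length(prep$liveRows), m)
    for (u in seq_len(config@nUnits)) {
      sites <- prep$amps[[u]]$sites
      if (!length(sites)) next
      onsets <- prep$spikes[[u]]
      onsets <- onsets[onsets > k0 - L & onsets < k0 + m]
      if (!length(onsets)) next
      trace <- numeric(m)
      for (o in onsets) {
        lo <- o - k0 + 1          # 1-based local onset
        src <- max(1L, 2L - lo):min(L, m - lo + 1L)
        trace[lo + src - 1L] <- trace[lo + src - 1L] + config@waveform[src]
      }
      rows <- match(sites, prep$liveRows)
      uv[rows, ] <- uv[rows, ] + outer(prep$amps[[u]]$amp, trace)
    }
    neural[prep$liveRows, ] <- quantizeUv(uv, config@lsbUv)
  }
  aux <- matrix(0L, nAuxChannels(lay), m)
  aux[config@gpioAuxChannel + 1L, ] <-
    gpioWords(m, config@gpioPattern, config@sampleRate, lay@gpioRate,
              startSample = k0)
  new("ModuleSession", experimentId = config@experimentId,
      moduleId = config@moduleId,
      sampleIndex = (config@startIndex + k0 + seq_len(m) - 1) %% 2^32,
      chipLive = rep(prep$mask, m), neural = neural, aux = aux, layout = lay)
}

#' Generate a synthetic session
#'
#' Runs the generative model of [simConfig()]: per-unit Poisson spike
#' trains rendered onto the site grid with exponential spatial decay, over
#' a white Gaussian noise floor, quantized to 16-bit codes. Dead chips
#' (and chips beyond `nChips`) carry zero filler with their chip-live bit
#' clear; the designated auxiliary slot carries the 2 kHz GPIO words; the
#' sample index starts at `startIndex` and wraps at 2^32.
#'
#' With a `path`, samples are generated and written chunk-by-chunk through
#' [sessionSink()] in constant memory; otherwise the whole session is
#' returned in memory (sized about `2 * 2240 * durationSamples` bytes).
#'
#' @param config a [SimConfig-class].
#' @param path optional output file; written via [sessionSink()].
#' @return the [ModuleSession-class] (no `path`), or invisibly a list with
#'   `path`, `nSamples` and `unitPositions`.
#' @examples
#' cfg <- simConfig(nChips = 1, durationSamples = 1000, seed = 42)
#' f <- tempfile()
#' generateSession(cfg, f)
#' file.size(f) == 1000 * 4096
#' @export
generateSession <- function(config, path = NULL) {
  validObject(config)
  withSeed(config@seed, {
    prep <- simPrepare(config)
    total <- config@durationSamples
    if (is.null(path)) {
      chunks <- list()
      k0 <- 0
      while (k0 < total) {
        m <- min(SIM_CHUNK, total - k0)
        chunks[[length(chunks) + 1L]] <- simChunk(config, prep, k0, m)
        k0 <- k0 + m
      }
      out <- chunks[[1L]]
      if (length(chunks) > 1L)
        out <- initialize(out,
          sampleIndex = unlist(lapply(chunks, sampleIndex)),
          chipLive = unlist(lapply(chunks, chipLive)),
          neural = do.call(cbind, lapply(chunks, neuralData)),
          aux = do.call(cbind, lapply(chunks, auxData)))
      out
    } else {
      sink <- sessionSink(path, prep$layout)
      k0 <- 0
      while (k0 < total) {
        m <- min(SIM_CHUNK, total - k0)
        sink$append(simChunk(config, prep, k0, m))
        k0 <- k0 + m
      }
      n <- sink$close()
      invisible(list(path = path, nSamples = n,
                     unitPositions = prep$unitPositions))
    }
  })
}
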