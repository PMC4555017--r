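---
title: "The direct-to-drive stream format: codec, budgets, simulation and integrity checking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The direct-to-drive stream format: codec, budgets, simulation and integrity checking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodaq)
```

## The system being modeled

A direct-to-drive acquisition module digitizes 1024 extracellular channels
(32 amplifier chips of 32 channels each) at 30 kS/s and 16-bit depth and
writes the stream straight to a SATA drive, with no computer in the data
path. Alongside the neural channels each chip contributes 3 auxiliary
channels, which carry chip registers or the state of the module's 16 GPIO
lines, the latter sampled at 2 kHz. A copy of the data is distributed over
gigabit Ethernet as UDP datagrams for live inspection; the drive holds the
authoritative record.

`neurodaq` is a software re-implementation of that data model: the on-disk
codec (bit-exact), the rate/capacity arithmetic, a generative simulator of
the acquisition front end, the post-hoc integrity validator, the datagram
path with loss, and the multi-module synchronization/merge scheme. It
contains no hardware code; everything runs on ordinary files and in-memory
objects.

## The record format

One complete module sample is

| section  | bytes | content                                                   |
|----------|------:|-----------------------------------------------------------|
| metadata |    20 | experiment id (u64), module id (u32), sample index (u32), chip-live mask (u32) |
| neural   |  2048 | 1024 u16 words, chip-major                                 |
| aux      |   192 | 96 u16 words, chip-major (3 per chip)                      |
| padding  |  1836 | zeros                                                      |

padded to a fixed 4096-byte record, written in blocks of 128 samples
(512 KiB). The experiment id is a UNIX UTC timestamp shared by every module
in an acquisition session; the module id is the bottom 32 bits of a MAC
address; the sample index is a sequential counter that wraps modulo
2^32 (about 39 h at 30 kS/s); the chip-live mask says which chips'
channels carry signal rather than filler.

Two points are conventions of this package, because the format description
we implement fixes field sizes and order but not bit-level details:

* **Endianness and packing.** All integer fields are little-endian and
  packed with no gaps, in the listed order. This is a single constant in
  the codec and is exercised bit-for-bit by the tests.
* **Padding granularity.** Padding is applied per sample (to 4096 bytes),
  not per block. This is the only reading consistent with both the
  aggregate rate (4096 x 30 000 = 122.88 MB/s in decimal units) and the
  padding fraction of 44.8% (1836/4096).

The fixed record size is what makes the rest of the package simple: the
k-th sample starts at byte `4096 k`, so `seekSample()` is O(1), sessions
are scanned in bounded chunks, and a session of N whole blocks occupies
exactly `N * 524288` bytes.

```{r}
recordLayout()
```

## Budget arithmetic

`dataRate()`, `recordingCapacity()`, `metadataOverheadPct()`,
`paddingPct()`, `perChipRateMbit()`, `rolloverHours()`,
`extraChannelCapacity()` and `sataHeadroom()` are closed forms over the
layout. Three choices deserve a note:

* Storage units are decimal (1 MB = 10^6 B, 1 GB = 10^9 B); a 512 GB drive
  then holds `floor(512e9/4096)` = 125 000 000 samples, i.e. "up to
  70 min".
* The two overhead figures use different denominators on purpose: metadata
  is quoted against the 2240-byte channel payload (20/2240 = 0.9%) while
  padding is quoted against the full 4096-byte record (1836/4096 = 44.8%).
  These are the denominators that reproduce the published figures; no
  single denominator reproduces both.
* The padding headroom of 831 extra neural channels uses continuous
  proportional accounting — each added neural channel costs its own
  2 bytes plus proportional aux (2 x 96/1024 B) and metadata (20/1024 B),
  2.20703125 B in total. Whole-chip accounting cannot reproduce this
  figure (26 more chips would need 1840 B > 1836 B).

## The synthetic session generator

`generateSession()` emulates what the front end digitizes. Its defaults
are the study conditions of the system the package models; they are set
once in `simConfig()` and are not tuned per analysis.

* **Noise floor**: white Gaussian noise, 3.9 µV RMS — the measured
  input-referred noise of the complete powered-on system. The published
  figure was measured in a 600–9700 Hz band; we generate white noise and
  apply no generation-side filter, so the configured RMS is the total RMS.
  Band-limited measurement belongs to analysis, not generation.
* **Amplifier scale**: `lsbUv = 0.195` µV per ADC code, the conventional
  scale of the amplifier family the module uses; the format itself does
  not fix it, so it is a parameter. Mid-scale code 32768 is 0 µV;
  quantization uses R's `round()` (round-half-even) and saturates at the
  rails.
* **Spiking**: each unit fires as a homogeneous Poisson process
  (`firingRateHz`, default 5 Hz — a typical cortical single-unit rate) and
  is rendered onto the site grid with amplitude `peak * exp(-d/decay)`.
  The default template is a ~1 ms biphasic waveform with a 150 µV negative
  peak; `spatialDecayUm = 25` µm makes a unit visible on several
  neighbouring sites of an 11.5 µm-pitch, 4-column close-packed grid —
  the spatially oversampling footprint such probes are built for.
* **GPIO**: the 16-line state is evaluated on the 2 kHz tick grid and held
  for 15 consecutive 30 kS/s samples in one designated aux slot
  (configurable). The format says GPIO is recorded among the auxiliary
  channels at 2 kHz but not how it maps onto 30 kS/s slots; the
  hold-and-embed scheme is our documented convention.
* **Dead chips** carry zero filler with their chip-live bit clear.
  Decoders must rely on the mask, never on content, so the filler value is
  deliberately unspecified by the format; zeros keep sessions compressible
  and diffs readable.
* **Determinism**: generation is a pure function of (config, seed);
  equal seeds give byte-identical session files. Samples are produced in
  fixed 4096-sample chunks, so the in-memory and streamed-to-file paths
  emit identical bytes.

What the generator does *not* emulate: bursting and refractory structure,
electrode drift, correlated or 1/f noise, amplifier filtering, and spike
waveform variability. Passing statistical tests on generated sessions
therefore validates the codec/validator/budget machinery and the
generator's own contracts — it says nothing about spike sorting or other
analyses of real recordings.

## The integrity validator

`validateSession()` re-implements the post-acquisition check used to
demonstrate lossless capture: a single sequential pass verifying that

a. the experiment and module identifiers never change,
b. the sample index increments by exactly 1 modulo 2^32 (a rollover is
   not a skip),
c. every padding byte is zero,
d. the record count matches an expected byte count when one is given, and
e. any trailing remainder shorter than one record is flagged.

Design choices: index stagnation (`INDEX_REPEAT`) is distinguished from
jumps (`INDEX_SKIP`) because repeats are an independent failure mode;
validation never fails fast — the full error census with 0-based record
ordinals is kept for forensics; and a mid-session change of the chip-live
mask is treated as an identity error by default (`allowChipLiveChange`
opts out) because the format does not specify whether chips may
legitimately drop out mid-session. `diffSessions()` covers the
copy-verification use case after downloading a drive.

## The datagram path

The format's network plane sends either snapshots of all 1024 channels of
one sample or a continuous stream of selected channels, as UDP datagrams
whose delivery is not guaranteed. The payload layout is not part of the
published format, so `serializePacket()` documents this package's own
little-endian wire dialect (magic `NDQ1`, 30-byte header). The default
payload cap of 720 words keeps each datagram at or below 1470 bytes — one
standard Ethernet frame after UDP/IP headers. `reassemble()` implements
receiver semantics: tolerant of reordering and duplication, never blocking
on loss, with every missing fragment or sample enumerated in a gap report.
The control plane (start/stop over TCP) is deliberately not modeled as a
protocol; its reliability contrast with UDP is captured by the loss tests.

## Synchronization and merging

Scaling beyond 1024 channels replicates modules, which raises clock
alignment. `simulateTimestamps()` compares:

* `FREE`: each module samples at `rate * (1 + drift)`; pairwise skew grows
  linearly at the drift difference — 50 ppm for 30 min accumulates to
  90 ms, three thousand sample periods.
* `PULSED`: a master distributes a sample-start pulse at every 30 kHz
  sample; skew is bounded by latch-delay spread plus edge jitter
  (sub-microsecond for 100 ns jitter) and drift never accumulates.
* `START_ONLY`: a single aligning start pulse, after which clocks
  free-run. The published description is ambiguous between the per-sample
  and start-only readings; both are provided so they can be compared, and
  the per-sample reading is the one that achieves sample-period
  synchronization.

Because sample times are closed forms in the ordinal, the simulator
evaluates exactly on any subset of ordinals; the tests evaluate 30
simulated minutes on tens of thousands of ordinals rather than all
54 million, which changes nothing but the resolution of the maximum.

`mergeSessions()` reconstructs a combined dataset keyed on
(experiment id, unwrapped sample index), module-major in the channel
dimension, with explicit `NA` gaps (and a gap table) where a module misses
a sample — never a silent misalignment.

## Numerical representation

R has no native unsigned 64-bit integer, so the 64-bit experiment id and
all unwrapped indices are held as doubles, which are exact below 2^53 —
five orders of magnitude beyond a UNIX-seconds id and ample for any
unwrapped counter. 32-bit fields are held as doubles and split into
16-bit words at the codec boundary; all payload words are R integers in
0..65535. These bounds are enforced by class validity and codec range
checks.

## Problem sizes in the test suite

The statistical contracts are exercised at sizes chosen to make the
assertions sharp while keeping the suite quick on one CPU: 1000-sample
randomized codec round trips, 5000-record fault-injection sessions,
10^5-sample noise-floor sessions (RMS tolerance 5%), 3 s single-unit
sessions at 15 Hz for threshold recovery (4-sigma Poisson band), 10^4
packets at 10% loss (4-sigma binomial band), and 30 simulated minutes of
clock drift. Each of these is a statement about the generative model's
parameters, not about wall-clock constraints; larger sessions only narrow
the bands.
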