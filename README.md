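# neurodaq

Tools for the raw sequential stream format written by direct-to-drive
neural data acquisition modules — FPGA-based recorders that digitize 1024
extracellular channels at 30 kS/s and 16-bit depth and write them straight
to a SATA drive, with no computer in the data path. The package is aimed
at people who work with such streams (or want to prototype against them
without hardware): it reads and writes the format bit-exactly, checks
stored sessions for integrity, simulates realistic sessions, models the
UDP distribution path, and simulates multi-module clock synchronization
and dataset merging.

## The data model

One *complete module sample* (one 30 kHz time point) is stored as a fixed
4096-byte record:

```
20 B metadata | 2048 B neural (1024 u16, chip-major) | 192 B aux (96 u16) | 1836 B zeros
```

The metadata is an 8-byte experiment identifier (UNIX UTC seconds shared
by the whole acquisition session), a 4-byte module identifier, a 4-byte
sample index (sequential, wraps mod 2^32 ≈ 39 h at 30 kS/s), and a 4-byte
chip-live mask (bit *i* set ⇔ amplifier chip *i* active). Records are
written in 128-sample blocks as a single sequential stream — no file
system, no headers. Everything else follows from the arithmetic of this
layout:

* aggregate rate 4096 B × 30 000 /s = **122.88 MB/s**, within the
  187.5 MB/s of SATA 1;
* a 512 GB drive holds ⌊512·10⁹/4096⌋ = 125 000 000 samples ≈ **70 min**;
* metadata is 20/2240 = **0.9 %** of the channel payload; padding is
  1836/4096 = **44.8 %** of the record, headroom for **831** additional
  neural channels (at 2.207 B marginal cost per channel, aux and metadata
  included).

The integrity contract is the one used to demonstrate lossless capture:
constant identifiers, a sample index that increments by exactly 1 mod 2^32
(rollover is not a skip), all-zero padding, and a record count that
matches the storage that held it.

## Worked example

```r
library(neurodaq)

lay <- recordLayout()
lay
#> RecordLayout: 4096 B/record = 20 meta + 2048 neural + 192 aux + 1836 pad
#>    1024 neural + 96 aux channels @ 30000 S/s; 128 -sample blocks ( 524288 B)

dataRate(lay) / 1e6                        # 122.88   (MB/s)
recordingCapacity(lay, 512e9)$minutesCeil  # 70       (min on a 512 GB drive)
metadataOverheadPct(lay)                   # 0.9      (% of channel payload)
paddingPct(lay)                            # 44.8     (% of each record)
extraChannelCapacity(lay)                  # 831      (extra neural channels)

# simulate a 0.2 s session: 4 chips, two Poisson units over a 3.9 uV noise floor
cfg <- simConfig(nChips = 4, durationSamples = 6000, nUnits = 2,
                 firingRateHz = 8, experimentId = 1443700000,
                 moduleId = 314159, seed = 7)
f <- tempfile()
generateSession(cfg, f)
file.size(f)                               # 24576000 = 6000 x 4096 bytes

rep <- validateSession(f, expectedBytes = file.size(f))
cat(summarizeReport(rep), sep = "\n")
#> session: 6000 records (24576000 bytes, 0-byte remainder)
#> ids: experiment 1443700000, module 314159
#> index: 0 .. 5999
#> PASSED: no errors

# pull two neural channels and the GPIO aux slot as a SummarizedExperiment
se <- extractChannels(f, c(0, 1, 1024))
dim(se)                                    # 3 6000
```

`validateSession()` reports every violation with its 0-based record
ordinal (`INDEX_SKIP`, `INDEX_REPEAT`, `ID_CHANGE`, `NONZERO_PADDING`,
`TRUNCATED_TAIL`, `SIZE_MISMATCH`) instead of failing fast. The other
modules follow the same pattern: `packetizeSnapshot()` / `lossyChannel()`
/ `reassemble()` for the UDP plane, `simulateTimestamps()` / `maxSkew()`
for clock synchronization, `mergeSessions()` for multi-module
reconstruction.

A command-line driver wrapping these functions installs as
`exec/neurodaq`:

```sh
neurodaq generate --out s.dat --samples 6000 --chips 4 --seed 7
neurodaq validate s.dat --json
neurodaq budget --drive-gb 512
```

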