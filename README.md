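# ssvepuac

Frequency recognition for SSVEP brain–computer interfaces, with an
unsupervised adaptive classifier that learns per-frequency EEG templates
online from its own decisions.

## The problem

A steady-state visual evoked potential (SSVEP) BCI presents the user with
targets flickering at distinct frequencies; gazing at a target entrains an
occipital EEG response at that frequency and its harmonics, and the decoder's
job is to recover the gazed frequency from a short multichannel epoch.
The workhorse *training-free* decoder is filter-bank canonical correlation
analysis (FBCCA): the epoch is split into D sub-bands, each sub-band is
scored against sinusoidal references by canonical correlation, and the
squared correlations are combined as

ρ̃_f = Σ_{d=1..D} w(d) · ρ²_{SB,d},  w(d) = d^(−a) + b  (a = 1.25, b = 0.25),

with the decision going to the frequency of the largest ρ̃_f. FBCCA discards
every epoch after classifying it. Because SSVEPs are time- and phase-locked,
those discarded epochs carry reusable information: summing two same-frequency
epochs adds their stimulus-locked components coherently while the background
EEG adds incoherently.

The unsupervised adaptive classifier (UAC) implemented here exploits this.
It keeps a per-frequency template bank Z (initialized to zero). For each
incoming epoch X it forms the superimposed signals X_i = X + Z_i, computes
the template-augmented FBCCA score p_i = FBCCA(X_i, Y_i) and the static score
p′_i = FBCCA(X, Y_i), and decides by the integrated statistic

p̃_i = p′_i + w · p_i

(w = 0.45 for 40-class layouts, 0.65 for 12-class, both overridable). The
decided frequency's template is then updated by the halving recursion
Z′ = (X + Z)/2 — using the *estimated* label, so no calibration data are ever
needed. With w = 0, or with an all-zero bank, the UAC reduces exactly to
static FBCCA.

The package also provides a phase-locked synthetic SSVEP generator with
controlled SNR (so everything is testable without downloads), readers for the
two public dataset layouts (40-target Benchmark and 12-target UCSD, MATLAB v5
files), an evaluation harness replaying the sequential-block online protocol,
information-transfer-rate (ITR) summaries, and an integration-weight sweep.

## Worked example

Simulate a 12-target session (6 blocks, 1 s epochs at 256 Hz, −13 dB SNR) and
replay the online protocol, comparing the adaptive decoder with its static
FBCCA baseline on the same trials:

```r
library(ssvepuac)
voc <- ucsd_vocabulary()
cfg <- synth_config(voc, sampling_rate = 256, snr_db = -13, seed = 42)
ses <- generate_session(cfg, n_blocks = 6)
pr  <- run_sequential_protocol(ses, ucsd_preset())
summary(pr)
```

```
Overall: static 0.6667, adaptive 0.8194 (gain +0.1528)
 block    static  adaptive       gain
     1 0.6666667 0.7500000 0.08333333
     2 0.7500000 0.8333333 0.08333333
     3 0.5833333 0.5833333 0.00000000
     4 0.5833333 0.9166667 0.33333333
     5 0.6666667 0.9166667 0.25000000
     6 0.7500000 0.9166667 0.16666667
```

Both decoders saw identical epochs; the static column is plain FBCCA, the
adaptive column is the template classifier as its bank fills up. The gain
grows across blocks — the signature of the method: early blocks have mostly
empty templates (where the UAC *is* FBCCA), later blocks benefit from
accumulated same-frequency superposition. In bits per minute:

```r
information_transfer_rate(c(0.6667, 0.8194), n_targets = 12,
                          trial_time_s = trial_time_for_itr(1.0))
```

```
ITR static 60.5 -> adaptive 91.2 bits/min
```

Real recordings are decoded the same way after conversion, e.g.
`read_benchmark_subject("S1.mat")` (user-supplied download) yields the same
session object `run_sequential_protocol()` consumes.

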