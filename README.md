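# myocomp

Simulation and analysis pipeline for pattern-recognition myoelectric
prosthesis control and the compensatory trunk movement it induces.

## The problem

People with symbrachydactyly (missing or shortened fingers with an intact
wrist) are usually fitted with myoelectric hands whose socket immobilizes the
wrist. The shoulder and trunk then take over the wrist's role during
pick-and-place movements — the elbow rides high and the trunk tilts — and
this compensatory movement is a measurable burden. A wrist-sparing,
separate-type socket paired with a controller that distinguishes wrist motion
from hand motion should lower the elbow path and shrink the trunk-tilt
burden. `myocomp` implements both halves of the computation needed to study
this:

1. **Control.** Surface EMG from three forearm sites (extensor carpi
   radialis brevis, flexor carpi ulnaris, flexor carpi radialis) sampled at
   2,000 Hz is high-pass filtered at 50 Hz, cut into Hann-windowed frames of
   256 samples, Fourier transformed, and reduced to mean band powers over
   eight 50-Hz bands from 0 to 400 Hz — a 24-dimensional feature vector
   **x** per frame (3 channels × 8 bands). During instruction, frames taught
   with an intention *y* are buffered into teacher data Ψ = (**x**, *y*); a
   feed-forward network fitted on Ψ gives per-frame predictions ŷ; a
   recognition-stabilization filter turns the noisy stream of ŷ into a
   stable output *o* (the modal label of the last *w* frames, adopted only
   when its proportion reaches τ, otherwise holding the previous output);
   finally *o* maps to a hand command with the wrist classes excluded:
   grip → close, open → open, rest / wrist flexion / wrist extension → hold.

2. **Compensatory movement.** From pose landmarks (both shoulders, both
   elbows, 0.11-s frames) the trunk angle θ_k is the signed inclination of
   the inter-shoulder line; the distortion level of a trial is

   D(Θ) = Σ_{k=0}^{n} |θ_k|,

   the absolute frame sum over the trial. Trials are compared between socket
   conditions via elbow trajectories (resampled to the longest trial,
   averaged, SD ellipses at the five-equal-part checkpoints), base/end elbow
   heights at grasp and release, >10-s trial exclusion, distortion
   histograms with rank width 50 and normal overlays, t tests, and blocks
   moved per 30-s window.

Because no public recordings of this task exist, the package ships a
first-class synthetic-data module: a seeded EMG generator with
class-dependent band-power signatures (plus 50-Hz line interference,
sensor noise, crosstalk) and a task-kinematics generator whose presets
encode the published per-participant height and distortion summaries
(`"table1_C"`, `"table2_D"`).

## Worked example

```r
library(myocomp)

scenario <- make_benchmark_scenario("table1_C", seed = 1)

# closed-loop control: teach, train, estimate on an independent recording
cs <- run_control_sim(scenario)
cs$summary$feature_dim        # 24
cs$summary$heldout_accuracy   # 1

# condition comparison at 200 trials per condition
mv <- run_move_analysis(scenario, n_trials = 200)
mv$report$base_height_difference_cm                  # 22.9
mv$report$conditions$conventional$distortion_mean    # 194.375
mv$report$conditions$separate$distortion_mean        # 95.40176
mv$report$conditions$conventional$blocks_per_30s     # 4.604651
mv$report$conditions$separate$blocks_per_30s         # 5.527778
```

The base-height difference of 22.9 cm says the conventional socket forces
the elbow that much higher at the grasp point than the separate socket; the
distortion means (≈194 vs ≈95) say the trunk-tilt burden roughly halves; the
block counts (≈4.6 vs ≈5.5 per 30 s) say throughput improves.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (simulate → control → kinematics → evaluation), writing tables and
figures under `results/`:

```sh
Rscript analysis/01_simulate.R 1
Rscript analysis/02_control.R 1
Rscript analysis/03_kinematics.R 1
Rscript analysis/04_evaluation.R 1
```

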