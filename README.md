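# gaitresilience

Resilience of locomotor behavior to rhythmic auditory perturbations.

When a walker synchronizes their steps to a metronome and the beat is
unexpectedly delayed, two recoveries unfold on different timescales: the
footfalls re-align with the beat, and the body's center of mass (COM)
returns to its steady-state movement pattern. `gaitresilience` implements a
complete pipeline to quantify both, from raw marker kinematics (100 Hz,
sacrum + heel/toe markers) and an individualized metronome schedule, for
movement scientists studying sensorimotor synchronization, dynamic
stability and fall risk.

## The method in brief

1. **Gait events.** Heel strikes and toe offs from foot-velocity: stance is
   a low-velocity window of the foot-centre vertical trace; the heel strike
   is its position minimum. Step time = heel contact to contralateral heel
   contact.
2. **Stimulus.** A subject-specific metronome whose inter-beat interval
   (IBI) equals the mean baseline step time; five consecutive intervals are
   each lengthened by 20 × the subject's baseline step-time SD ("20×SD
   rule"), around 3 min into the track. Rendered to WAV (0.1 s, 440 Hz
   tones).
3. **State space.** The sacral vertical displacement — a COM surrogate —
   is zero-phase low-pass filtered (4th order, 5 Hz), trimmed, demeaned,
   and reconstructed by time-delay embedding
   `[x(t), x(t+τ), x(t+2τ)]`, with τ from the first average-mutual-
   information minimum and the dimension checked by false nearest
   neighbours.
4. **Steady-state boundary.** Baseline walking traces a closed loop;
   an 8-term Fourier curve `M(θ)` over the angle about the centroid
   summarizes it, and per-degree ellipses (axes = the two largest local
   standard deviations of the 50 nearest vectors) stack into nested tori
   `T_1σ ⊂ T_2σ ⊂ T_3σ`.
5. **Response parameterization.** From the deviation series `D(t)` and the
   per-sample torus labels: lag time (onset → first ≥ 0.1 s excursion
   beyond `T_2σ`), peak time, peak magnitude (mm), and COM recovery time
   (peak → sustained residence in `T_2σ` for 5 cycles, tolerating 4
   outliers of ≤ 0.01 s). Footfall synchrony recovers when 3-step moving
   means of the step-time asynchrony stay within the pre-perturbation
   mean ± 2 SD band for 8 consecutive windows (= 10 steps).
6. **Group statistics.** BCa bootstrap of the paired COM-vs-synchrony
   recovery difference; repeated-measures ANOVA on τ and d across trials.

A synthetic-data module generates complete subjects (markers, metronome,
perturbation responses) with known ground truth, so every stage is testable
without participant data.

## Worked example

One synthetic subject, full pipeline:

```r
library(gaitresilience)

m <- subject_model(seed = 11)                       # ground-truth walker
bw1 <- generate_trial(m, "BW", 360, trial = "BW1", seed = m$seed)
track <- build_metronome(m$mean_step_time, m$step_sd, 360)
cw  <- generate_trial(m, "CW", 360, track = track, trial = "CW",  seed = m$seed + 1L)
bw2 <- generate_trial(m, "BW", 360, trial = "BW2", seed = m$seed + 2L)

res <- run_subject(bw1, cw, bw2, track = track, subject = "S11")

track
#> <metronome_track: 598 beats, IBI 0.600 s, 5 perturbed intervals (+0.260 s each) from 180.00 s>
res$resilience
#> <resilience_metrics: lag 1.10 s, peak 0.84 s, magnitude 28.1 mm, recovery 11.30 s>
res$synchrony
#> <synchrony_metrics: peak adjustment 0.280 s at step 304, recovered in 2.86 s>
round(res$occupancy$CW2, 1)
#>   T1   T2   T3  OUT
#> 35.5 26.3 11.3 27.0
```

Reading: the perturbation lengthened five beat intervals by 0.26 s each.
The subject's COM left the 2σ steady-state boundary 1.10 s after the
perturbation began, deviated at most 28.1 mm from the reference trajectory
(this subject's injected ground-truth transient peak is 28 mm), and took
11.3 s from that maximum to settle back. The footfalls, whose largest
single-step adjustment was 0.28 s, re-synchronized 2.86 s after the peak
adjustment — footfall synchrony recovered well before COM kinematics, and
during the recovery phase (CW2) the trajectory spent 27% of its time beyond
the 3σ boundary versus ~0% before and after.

## The analysis workflow

Numbered drivers under `analysis/` reproduce the full synthetic study and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # 20 subjects, parameters + example data
Rscript analysis/02_run_pipeline.R      # per-subject metrics table
Rscript analysis/03_group_stats.R       # summaries, bootstrap CI, ANOVA on tau/d
```

The cohort contains 15 subjects with an injected COM transient, 5 with
none, and (among those 5) 2 who never adjust their step timing — the
phenotype structure the pipeline must recover.

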