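# CSV formats

All files are RFC-4180 CSV, UTF-8, dot decimal separator. Lines starting
with `#` are header comments carrying units and metadata; numeric cells are
written with 17 significant digits so reads round-trip bit-identically.

## Trial files (`<base>_grf.csv`, `<base>_kin.csv`)

One trial is split over two files because the force platform (1000 Hz) and
the motion capture (200 Hz) sample at different rates. Header comments in
each: `# subject:`, `# condition:`, `# mass_kg:`, `# rate_hz:`.

`<base>_grf.csv` columns:

| column   | units | description                  |
|----------|-------|------------------------------|
| `time_s` | s     | strictly increasing, uniform |
| `grf_z_N`| N     | vertical ground reaction force |

`<base>_kin.csv` columns: `time_s` (s), `ankle_angle_deg`, `knee_angle_deg`,
`hip_angle_deg` (degrees; dorsiflexion/flexion positive), and
`ankle_moment_Nmkg`, `knee_moment_Nmkg`, `hip_moment_Nmkg` (Nm/kg;
dorsiflexion/flexion moments positive). Time zero is the first stance frame.

Example (`S001_pre_kin.csv`):

```
# subject: S001
# condition: pre
# mass_kg: 65.390000000000001
# rate_hz: 200
time_s,ankle_angle_deg,knee_angle_deg,hip_angle_deg,ankle_moment_Nmkg,knee_moment_Nmkg,hip_moment_Nmkg
-0.05,9.2300000000000004,19.170000000000002,35.869999999999997,0,0,0
...
```

## Cohort files

- `cohort_manifest.csv`: `subject`, `condition`, `base`, `mass_kg`,
  `grf_rate_hz`, `kin_rate_hz` — one row per trial.
- `ground_truth.csv` (synthetic cohorts): tidy `subject`, `condition`,
  `variable`, `value`; angles in degrees, moments Nm/kg, powers W/kg,
  works J/kg, stance duration s, mass kg.

## Analysis outputs (under the run directory)

- `discrete_variables.csv`: one row per subject x condition with
  `<joint>_ic`, `<joint>_max_angle`, `<joint>_min_angle`, `<joint>_rom`
  (deg), `<joint>_peak_pos_power`, `<joint>_peak_neg_power` (W/kg),
  `<joint>_peak_pos_moment`, `<joint>_peak_neg_moment` (Nm/kg),
  `<joint>_pos_work`, `<joint>_neg_work`, `<joint>_total_work` (J/kg),
  `stance_duration` (s).
- `group_comparison.csv`: per variable, pre/post mean and SD, mean paired
  difference, paired t, two-sided p, n, Shapiro-Wilk p on the differences.
- `waveform_tests.csv`: per signal (angle/moment/power), joint and stance
  node (percent): paired t, permutation family-wise threshold, in-cluster
  flag.
- `plsr_q2_trace.csv`: per candidate component H: PRESS, SS, SS(H-1), Q2,
  accepted flag.
- `plsr_summary.csv`: components kept and train/test prediction accuracy
  (100 x (1 - RMSE/range), averaged over responses).
- `plsr_coefficients.csv`: original-unit slopes, one row per predictor.
- `plsr_predictions.csv`: in-sample predicted joint works (J/kg).
- `predictor_stats.csv`: per predictor average, max, min, range (deg).
- `perturbation_grid.csv`: level label, range fraction `k`, and the
  perturbed value per predictor (`min + k * dif`; full precision — round to
  2 decimals for display).
- `sensitivity_predictions.csv`: predictor, level, perturbed value,
  response, predicted value (J/kg), others held at their averages.
- `direction_summary.csv`: sign of the predicted response change from the
  lowest to the highest level per (predictor, response).
- `manifest.csv`: configuration hash, seeds, cardinalities, package version.
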