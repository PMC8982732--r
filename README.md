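# recoverhome

Passive home monitoring of recovery after hip or knee replacement surgery,
from two channels a wrist-worn wearable provides through in-home Bluetooth
Low-Energy (BLE) gateways: received signal strength (RSSI) to each gateway,
and tri-axial acceleration at a nominal 25 Hz. The package is aimed at
researchers in digital health and remote patient monitoring who want to turn
those streams into clinically interpretable trends — where in the home a
patient spends their time, how much they move, their rest–activity rhythm,
and what postures dominate their day — and to compare those trends with
patient-reported outcome measures (PROMs) such as the Oxford Hip Score.

Because real in-home patient recordings are privacy-sensitive, the package
ships a synthetic smart-home generator (homes, circadian routines, sensor
channels, annotation protocols, gateway failures, PROM fixtures) with the
statistical structure the analyses assume, so the entire pipeline is
reproducible and tested end to end without any private data.

## What it computes

* **Indoor localisation by RSSI fingerprinting.** Half-open 1-s windows give,
  per gateway, the sum, mean, min, max and variance of RSSI (silent gateways
  substituted with the out-of-range constant −100 dB). A multilayer
  perceptron with three 10-node hidden layers, tuned by grid search over
  solver/learning rate/momentum on a stratified 60/40 split, maps the
  5·G-dimensional fingerprint to a room. Per-second timelines, daily
  occupancy percentages and gateway-health/outage diagnostics follow.
* **Actigraphy.** Acceleration magnitude `A = sqrt(x² + y² + z²)`, 1-min
  epochs with zero (or interpolating) imputation of out-of-range gaps, and
  the non-parametric circadian metrics: least-active 5-h (L5) and most-active
  10-h (M10) windows of the average 24-h profile, interdaily stability

      IS = n · Σ_h (x̄_h − x̄)² / ( p · Σ_i (x_i − x̄)² ),

  intradaily variability

      IV = n · Σ_{i≥2} (x_i − x_{i−1})² / ( (n−1) · Σ_i (x_i − x̄)² ),

  relative amplitude `RA = (M10 − L5)/(M10 + L5)`, and ΔT, the signed
  circular offset between L5 onset and self-reported sleep onset.
* **Posture/ambulation classification.** 6-s windows with a 3-s step (150
  samples at 25 Hz) yield 18 features (per-axis mean/sd, gravity-free
  mean/sd, and a normalised 10-bin histogram of the gravity-free signal on
  [−4, 4] g) classified into {lay down, sit, stair, stand, walk} by a
  100-tree Gini random forest, evaluated by stratified 5-fold
  cross-validation.
* **Reporting.** Hourly modal location/activity grids with L5/M10 highlight
  bands, the 75th-percentile movement spiral, PROM comparison tables, and a
  fully seeded `run_pipeline()` that writes every artefact to a directory.

## Worked example

Train a room classifier from a simulated technician walk-around of a 7-room,
5-gateway home, then profile a week of a control participant:

```r
library(recoverhome)

home  <- generate_home(7, 5, seed = 1)
wa    <- simulate_walkaround(home, sim_config(seed = 2, shadow_sd = 3))
feats <- featurise_rssi(wa$stream, home$gateways$gateway)
model <- train_localiser(label_features(feats, wa$annotations), seed = 1)
model
#> <localiser> rooms: bathroom, bedroom, dining room, hall, kitchen, living room, study
#>   test accuracy 0.937  weighted F1 0.937  support 284

routine <- generate_routine("control", 7, seed = 3)
stream  <- simulate_stream(home, routine, sim_config(seed = 4, accel_hz = 5))
prof    <- actigraphy_profile(epochise(magnitude(stream)))
prof
#> <actigraphy_profile> L5 23:32 (0.0028 g)  M10 13:09 (0.0567 g)
#>   IS 0.357  IV 1.163  RA 0.905  over 7 day(s)
delta_t(prof, "23:00")
#> [1] 32
```

Reading this: the held-out fingerprint accuracy is 93.7 % over 284 test
windows; the participant's least-active five hours start at 23:32 — 32
minutes after their self-reported 23:00 bedtime — with a strong rest/active
contrast (RA 0.91) and an intradaily variability of 1.16 on hourly movement.
`run_pipeline(list(profile = "withdrawing", days = 14), "out/")` runs the
whole chain (localisation, actigraphy, activity, figures, PROM table) into
`out/`.

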