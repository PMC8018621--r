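{
  "daily_metrics.csv": [
    "day", "level", "ci_mean", "ci_sd_across_reps", "q",
    "n_treated", "n_arrivals"
  ],
  "events.csv": [
    "replication", "patient_id", "acuity", "path", "t0_arrival",
    "t3_treatment_start", "depart_time", "arrival_day", "censored_flag"
  ],
  "summary.json": [
    "scenario", "growth_ratio", "replications", "seed", "horizon_days",
    "max_ci", "max_ci_of_rep_max", "recovery_days", "n_patients",
    "censored_fraction"
  ],
  "fit.json": ["breakpoint", "coefficients", "points"]
}
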