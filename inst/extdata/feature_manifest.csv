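name,group,description
baseline_bpm,baseline,Modal FHR level of the segment (bpm)
baseline_drift_bpm_per_min,baseline,Linear trend of FHR over the segment (bpm/min)
bradycardia_fraction,baseline,Fraction of samples below 110 bpm
tachycardia_fraction,baseline,Fraction of samples above 160 bpm
stv_mean_bpm,variability_short,Mean over minutes of mean absolute successive difference (bpm)
stv_median_bpm,variability_short,Median over minutes of short-term variability (bpm)
stv_min_bpm,variability_short,Minimum per-minute short-term variability (bpm)
stv_max_bpm,variability_short,Maximum per-minute short-term variability (bpm)
stv_low_fraction,variability_short,Fraction of minutes with short-term variability below 1 bpm
ltv_mean_bpm,variability_long,Mean per-minute amplitude (max-min excluding events) (bpm)
ltv_median_bpm,variability_long,Median per-minute amplitude (bpm); the aggregate variability
ltv_min_bpm,variability_long,Minimum per-minute amplitude (bpm)
ltv_max_bpm,variability_long,Maximum per-minute amplitude (bpm)
ltv_reduced_fraction,variability_long,Fraction of minutes with amplitude below 5 bpm
ltv_marked_fraction,variability_long,Fraction of minutes with amplitude above 25 bpm
accel_count,acceleration,Number of accelerations (>=15 bpm for >=15 s)
accel_total_duration_s,acceleration,Total acceleration time (s)
accel_mean_duration_s,acceleration,Mean acceleration duration (s)
accel_mean_amplitude_bpm,acceleration,Mean peak height above baseline (bpm)
accel_max_amplitude_bpm,acceleration,Maximum peak height above baseline (bpm)
early_decel_count,deceleration_early,Number of early decelerations (nadir within 15 s of UC peak)
early_decel_total_duration_s,deceleration_early,Total early-deceleration time (s)
early_decel_mean_depth_bpm,deceleration_early,Mean nadir depth below baseline (bpm)
early_decel_mean_lag_s,deceleration_early,Mean nadir lag vs UC peak (s)
late_decel_count,deceleration_late,Number of late decelerations (nadir 15-60 s after UC peak)
late_decel_total_duration_s,deceleration_late,Total late-deceleration time (s)
late_decel_mean_depth_bpm,deceleration_late,Mean nadir depth below baseline (bpm)
late_decel_mean_lag_s,deceleration_late,Mean nadir lag vs UC peak (s)
variable_decel_count,deceleration_variable,Number of variable decelerations (abrupt or contraction-independent)
variable_decel_total_duration_s,deceleration_variable,Total variable-deceleration time (s)
variable_decel_mean_depth_bpm,deceleration_variable,Mean nadir depth below baseline (bpm)
variable_decel_mean_lag_s,deceleration_variable,Mean nadir lag vs UC peak (s)
prolonged_decel_count,deceleration_prolonged,Number of prolonged decelerations (>=120 s)
prolonged_decel_total_duration_s,deceleration_prolonged,Total prolonged-deceleration time (s)
prolonged_decel_mean_depth_bpm,deceleration_prolonged,Mean nadir depth below baseline (bpm)
prolonged_decel_mean_lag_s,deceleration_prolonged,Mean nadir lag vs UC peak (s)
decel_count_total,deceleration_aggregate,Total decelerations of any type
decel_total_duration_s,deceleration_aggregate,Total deceleration time (s)
decel_max_depth_bpm,deceleration_aggregate,Deepest nadir below baseline (bpm)
decel_time_fraction,deceleration_aggregate,Fraction of segment time inside decelerations
uc_contraction_count,uterine,Number of detected contraction peaks
uc_mean_interval_s,uterine,Mean interval between contraction peaks (s)
uc_mean_amplitude,uterine,Mean contraction-peak height above channel minimum (relative units)
decel_per_contraction_ratio,uterine,Decelerations per detected contraction
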