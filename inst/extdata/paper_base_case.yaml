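schema_version: 1
horizon_days: 42
cohort_n: 10000
wtp_threshold: 45000.0
qaly_basis: horizon
combine_rule: max_disutility
probs:
  p_tolac_success: 0.666
  p_ventouse_given_success: 0.13
  p_morbidity:
    tolac_unassisted: 0.021390374331551
    tolac_ventouse: 0.021914648212226
    emergency_cs: 0.139388489208633
    ercd: 0.029
  p_death:
    tolac_unassisted: 0.0
    tolac_ventouse: 0.0
    emergency_cs: 0.0
    ercd: 0.0001
deliveries:
  tolac_unassisted:
    consumables: 104.439999999999998
    staff: 523.5
    baseline_los_days: 2
    drg_bed_day_rate: .na.real
    shared_days: 2
    complication_bed_day_rate: 883.0
  tolac_ventouse:
    consumables: 180.340000000000003
    staff: 573.75
    baseline_los_days: 3
    drg_bed_day_rate: 883.0
    shared_days: 2
    complication_bed_day_rate: 883.0
  emergency_cs:
    consumables: 173.060000000000002
    staff: 767.330000000000041
    baseline_los_days: 5
    drg_bed_day_rate: 1161.0
    shared_days: 2
    complication_bed_day_rate: 1161.0
  ercd:
    consumables: 130.680000000000007
    staff: 481.329999999999984
    baseline_los_days: 5
    drg_bed_day_rate: 1161.0
    shared_days: 2
    complication_bed_day_rate: 1161.0
profiles:
  tolac_unassisted:
    cpx: 0.256
    mob: 0.031
    pac: 0.072
    sac: 0.054
    disutility_per_day: 0.41
    duration_days: 7
  tolac_ventouse:
    cpx: 0.424
    mob: 0.031
    pac: 0.072
    sac: 0.054
    disutility_per_day: 0.58
    duration_days: 21
  emergency_cs:
    cpx: 0.424
    mob: 0.031
    pac: 0.072
    sac: 0.054
    disutility_per_day: 0.58
    duration_days: 21
  ercd:
    cpx: 0.424
    mob: 0.031
    pac: 0.072
    sac: 0.054
    disutility_per_day: 0.58
    duration_days: 21
complications:
  uterine_rupture:
    name: uterine_rupture
    addon_cost: 1235.329999999999927
    los_days: 5
    profile:
      cpx: 0.424
      mob: 0.031
      pac: 0.072
      sac: 0.054
      disutility_per_day: 0.58
      duration_days: 21
  hysterectomy:
    name: hysterectomy
    addon_cost: 905.940000000000055
    los_days: 11
    profile:
      cpx: 0.424
      mob: 0.031
      pac: 0.072
      sac: 0.054
      disutility_per_day: 0.58
      duration_days: 21
  operative_injury:
    name: operative_injury
    addon_cost: 355.25
    los_days: 6
    profile:
      cpx: 0.369
      mob: 0.031
      pac: 0.072
      sac: 0.054
      disutility_per_day: 0.53
      duration_days: 21
  blood_transfusion:
    name: blood_transfusion
    addon_cost: 596.629999999999995
    los_days: 5
    profile:
      cpx: 0.256
      mob: 0.031
      pac: 0.072
      sac: 0.054
      disutility_per_day: 0.41
      duration_days: 7
  endometritis:
    name: endometritis
    addon_cost: 49.5
    los_days: .na.integer
    profile:
      cpx: 0.16
      mob: 0.089
      pac: 0.072
      sac: 0.054
      disutility_per_day: 0.38
      duration_days: 14
morbidity_weights:
  tolac_unassisted:
    uterine_rupture: 0.168
    hysterectomy: 0.04
    operative_injury: 0.032
    blood_transfusion: 0.152
    endometritis: 0.608
  tolac_ventouse:
    uterine_rupture: 0.157894736842105
    hysterectomy: 0.052631578947368
    operative_injury: 0.052631578947368
    blood_transfusion: 0.157894736842105
    endometritis: 0.578947368421053
  emergency_cs:
    uterine_rupture: 0.148706896551724
    hysterectomy: 0.015086206896552
    operative_injury: 0.196120689655172
    blood_transfusion: 0.043103448275862
    endometritis: 0.59698275862069
  ercd:
    uterine_rupture: 0.0
    hysterectomy: 0.037931034482759
    operative_injury: 0.193103448275862
    blood_transfusion: 0.093103448275862
    endometritis: 0.675862068965517

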