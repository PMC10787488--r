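calendar:
  workdays:
  - Mon
  - Tue
  - Wed
  - Thu
  - Fri
  lab_open: '08:00'
  lab_close: '22:00'
  arrival_time: '07:00'
  start_weekday: Sun
horizon:
  warmup_days: 10
  observation_days: 61
  replications: 1000
resources:
  beds: 87
  labs: 2
  physicians_on_duty: 2
arrivals:
  TEP:
    mean: 2.446
    sd: 2.358
    regime: empirical
  CLEP:
    mean: 3.875
    sd: 2.684
    regime: empirical
  NEP:
    mean: 13.161
    sd: 5.99
    regime: empirical
procedure_classes:
- name: Paroxysmal AF ablation
  proportion: 0.183816183816184
  operative_time:
    mean: 204.947000000000003
    sd: 66.734999999999999
    min: 65.0
    max: 340.0
  cleanup:
    mean: 7.467
    sd: 7.477
    min: 2.0
    max: 40.0
  length_of_stay:
    mean: 5.05
    sd: 2.35
    min: 3.0
    max: 11.0
  preop_stay:
    mean: 2.0
    sd: 2.151
    min: 1.0
    max: 8.0
- name: Persistent AF ablation
  proportion: 0.095904095904096
  operative_time:
    mean: 208.687999999999988
    sd: 51.927
    min: 128.0
    max: 321.0
  cleanup:
    mean: 5.8
    sd: 2.833
    min: 2.0
    max: 11.0
  length_of_stay:
    mean: 3.375
    sd: 1.061
    min: 3.0
    max: 6.0
  preop_stay:
    mean: 1.375
    sd: 1.061
    min: 1.0
    max: 4.0
- name: PVC ablation
  proportion: 0.161838161838162
  operative_time:
    mean: 107.206000000000003
    sd: 40.630000000000003
    min: 35.0
    max: 202.0
  cleanup:
    mean: 6.963
    sd: 4.485
    min: 1.0
    max: 25.0
  length_of_stay:
    mean: 2.81
    sd: 1.209
    min: 2.0
    max: 7.0
  preop_stay:
    mean: 1.4
    sd: 0.681
    min: 0.0
    max: 3.0
- name: SVT ablation
  proportion: 0.175824175824176
  operative_time:
    mean: 99.066999999999993
    sd: 30.77
    min: 70.0
    max: 209.0
  cleanup:
    mean: 5.13
    sd: 2.117
    min: 1.0
    max: 10.0
  length_of_stay:
    mean: 2.478
    sd: 0.73
    min: 1.0
    max: 4.0
  preop_stay:
    mean: 1.25
    sd: 0.55
    min: 0.0
    max: 2.0
- name: AFlutter/PAC/AT ablation
  proportion: 0.058941058941059
  operative_time:
    mean: 212.544999999999987
    sd: 149.094999999999999
    min: 70.0
    max: 574.0
  cleanup:
    mean: 9.286
    sd: 9.032
    min: 1.0
    max: 28.0
  length_of_stay:
    mean: 4.0
    sd: 2.646
    min: 2.0
    max: 9.0
  preop_stay:
    mean: 1.333
    sd: 0.816
    min: 1.0
    max: 3.0
- name: GP ablation
  proportion: 0.021978021978022
  operative_time:
    mean: 99.0
    sd: 52.848999999999997
    min: 50.0
    max: 155.0
  cleanup:
    mean: 6.5
    sd: 2.121
    min: 5.0
    max: 8.0
  length_of_stay:
    mean: 2.5
    sd: 0.707
    min: 2.0
    max: 3.0
  preop_stay:
    mean: 2.0
    sd: 0.0
    min: 2.0
    max: 2.0
- name: PFO closure
  proportion: 0.021978021978022
  operative_time:
    mean: 35.332999999999998
    sd: 6.11
    min: 30.0
    max: 42.0
  cleanup:
    mean: 7.5
    sd: 3.536
    min: 5.0
    max: 10.0
  length_of_stay:
    mean: 3.0
    sd: 0.0
    min: 3.0
    max: 3.0
  preop_stay:
    mean: 1.0
    sd: 0.0
    min: 1.0
    max: 1.0
- name: ICD implant
  proportion: 0.014985014985015
  operative_time:
    mean: 99.25
    sd: 41.978999999999999
    min: 65.0
    max: 160.0
  cleanup:
    mean: 6.667
    sd: 2.887
    min: 5.0
    max: 10.0
  length_of_stay:
    mean: 5.0
    sd: 0.0
    min: 5.0
    max: 5.0
  preop_stay:
    mean: 1.0
    sd: 0.0
    min: 1.0
    max: 1.0
- name: Dual-chamber PM implant
  proportion: 0.058941058941059
  operative_time:
    mean: 104.063000000000002
    sd: 31.693000000000001
    min: 49.0
    max: 167.0
  cleanup:
    mean: 8.444000000000001
    sd: 4.773
    min: 2.0
    max: 15.0
  length_of_stay:
    mean: 4.5
    sd: 1.732
    min: 3.0
    max: 7.0
  preop_stay:
    mean: 2.0
    sd: 1.414
    min: 1.0
    max: 3.0
- name: CRT PM implant
  proportion: 0.036963036963037
  operative_time:
    mean: 190.199999999999989
    sd: 67.087000000000003
    min: 94.0
    max: 267.0
  cleanup:
    mean: 5.6
    sd: 3.362
    min: 2.0
    max: 10.0
  length_of_stay:
    mean: 6.6
    sd: 3.715
    min: 4.0
    max: 12.0
  preop_stay:
    mean: 2.2
    sd: 2.168
    min: 1.0
    max: 6.0
- name: Miscellaneous EP procedures
  proportion: 0.168831168831169
  operative_time:
    mean: 86.741
    sd: 54.488
    min: 27.0
    max: 305.0
  cleanup:
    mean: 6.6
    sd: 4.619
    min: 2.0
    max: 25.0
  length_of_stay:
    mean: 2.917
    sd: 1.165
    min: 2.0
    max: 5.0
  preop_stay:
    mean: 1.167
    sd: 0.577
    min: 1.0
    max: 3.0
weekday_allocations:
  Mon:
  - 0.727
  - 0.273
  Tue:
  - 0.184
  - 0.816
  Wed:
  - 0.5
  - 0.5
  Thu:
  - 0.532
  - 0.468
  Fri:
  - 0.292
  - 0.708
clep_los:
  mean: 5.427
  sd: 4.261
  min: 1.0
  max: 30.993000000000002
nep_los:
  mean: 3.758
  sd: 2.718
  min: 1.0
  max: 20.065999999999999
bed_policy: waitlist
seed: 20220501
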