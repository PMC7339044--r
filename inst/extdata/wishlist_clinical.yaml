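name: clinical
slack_delta: 0.001
prescription:
  pd_high: 64.6
  pd_low: 57.76
  n_fractions: 19
constraints:
- structure: PTV_High
  fun: max_dose
  limit:
    value: 105.0
    of: PD_High
- structure: PTV_High
  fun: mean_dose
  limit:
    value: 100.5
    of: PD_High
- structure: PTV_Low_minus_expanded_PTV_High
  fun: max_dose
  limit:
    value: 95.0
    of: PD_High
- structure: Shell50
  fun: max_dose
  limit:
    value: 50.0
    of: PD_High
- structure: rectum
  fun: max_dose
  limit:
    value: 102.0
    of: PD_High
- structure: anus
  fun: max_dose
  limit:
    value: 102.0
    of: PD_High
- structure: external
  fun: max_dose
  limit:
    value: 105.0
    of: PD_High
- structure: CTV_High
  fun: min_dose
  limit:
    value: 95.0
    of: PD_High
- structure: CTV_Low
  fun: min_dose
  limit:
    value: 95.0
    of: PD_Low
objectives:
- priority: 1
  structure: PTV_High
  fun: ltcp
  goal: 0.8
  sufficient: 0.8
  enabled: yes
  pd:
    value: 99.5
    of: PD_High
  alpha: 0.8
- priority: 2
  structure: PTV_Low_minus_RectumPRV
  fun: ltcp
  goal: 0.4
  sufficient: 0.4
  enabled: no
  pd:
    value: 100.0
    of: PD_Low
  alpha: 1.4
- priority: 3
  structure: PTV_Low
  fun: ltcp
  goal: 0.4
  sufficient: 0.4
  enabled: yes
  pd:
    value: 100.0
    of: PD_Low
  alpha: 1.4
- priority: 4
  structure: rectum
  fun: geud
  goal: 0.0
  sufficient: 0.0
  enabled: yes
  k: 7.7
- priority: 5
  structure: EntranceDose
  fun: max_dose
  goal:
    value: 20.0
    of: PD_Low
  sufficient:
    value: 20.0
    of: PD_Low
  enabled: yes
- priority: 5
  structure: Shell5
  fun: max_dose
  goal:
    value: 80.0
    of: PD_Low
  sufficient:
    value: 80.0
    of: PD_Low
  enabled: yes
- priority: 6
  structure: rectum
  fun: mean_dose
  goal: 5.0
  sufficient: 5.0
  enabled: yes
- priority: 7
  structure: anus
  fun: mean_dose
  goal: 5.0
  sufficient: 5.0
  enabled: yes
- priority: 8
  structure: Shell15
  fun: max_dose
  goal:
    value: 50.0
    of: PD_Low
  sufficient:
    value: 50.0
    of: PD_Low
  enabled: yes
- priority: 8
  structure: Shell25
  fun: max_dose
  goal:
    value: 30.0
    of: PD_Low
  sufficient:
    value: 30.0
    of: PD_Low
  enabled: yes
- priority: 9
  structure: bladder
  fun: mean_dose
  goal: 5.0
  sufficient: 5.0
  enabled: yes
- priority: 10
  structure: hip_left
  fun: max_dose
  goal: 40.0
  sufficient: 40.0
  enabled: yes
- priority: 10
  structure: hip_right
  fun: max_dose
  goal: 40.0
  sufficient: 40.0
  enabled: yes
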