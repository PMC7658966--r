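# Default synthetic five-injector study design.
# Line volumes and max_pressure scalars are illustrative placeholders with
# realistic orders of magnitude (PS lines small, RP lines several-fold
# larger); they are not vendor specifications.
days: 2
injectors:
  - injector_id: MedAcc
    pump_type: PS
    line_volume_ml: 6.0
    max_pressure: 10
    line_config: regular
  - injector_id: MedSol
    pump_type: PS
    line_volume_ml: 5.5
    max_pressure: 8
    line_config: regular
  - injector_id: CovOpt
    pump_type: PS
    line_volume_ml: 6.5
    max_pressure: 5
    line_config: regular
  - injector_id: UMiss
    pump_type: RP
    line_volume_ml: 95.0
    max_pressure: 4
    line_config: regular
  - injector_id: UMax3
    pump_type: RP
    line_volume_ml: 60.0
    max_pressure: 6
    line_config: regular
protocols:
  # vVol: variable volume at constant 5 ml/s flow
  - {protocol_id: vVol_15_Gadoterate,  cm_type: Gadoterate,  cm_volume_ml: 15, flow_rate_ml_s: 5.0, group: vVol}
  - {protocol_id: vVol_15_Gadoteridol, cm_type: Gadoteridol, cm_volume_ml: 15, flow_rate_ml_s: 5.0, group: vVol}
  - {protocol_id: vVol_10_Gadoterate,  cm_type: Gadoterate,  cm_volume_ml: 10, flow_rate_ml_s: 5.0, group: vVol}
  - {protocol_id: vVol_10_Gadoteridol, cm_type: Gadoteridol, cm_volume_ml: 10, flow_rate_ml_s: 5.0, group: vVol}
  - {protocol_id: vVol_5_Gadoterate,   cm_type: Gadoterate,  cm_volume_ml: 5,  flow_rate_ml_s: 5.0, group: vVol}
  - {protocol_id: vVol_5_Gadoteridol,  cm_type: Gadoteridol, cm_volume_ml: 5,  flow_rate_ml_s: 5.0, group: vVol}
  # cVol: constant 10 ml volume at variable flow (10 ml @ 5 ml/s is shared
  # with the vVol grid and listed once above)
  - {protocol_id: cVol_2.5_Gadoterate,  cm_type: Gadoterate,  cm_volume_ml: 10, flow_rate_ml_s: 2.5, group: cVol}
  - {protocol_id: cVol_2.5_Gadoteridol, cm_type: Gadoteridol, cm_volume_ml: 10, flow_rate_ml_s: 2.5, group: cVol}
  - {protocol_id: cVol_1_Gadoterate,    cm_type: Gadoterate,  cm_volume_ml: 10, flow_rate_ml_s: 1.0, group: cVol}
  - {protocol_id: cVol_1_Gadoteridol,   cm_type: Gadoteridol, cm_volume_ml: 10, flow_rate_ml_s: 1.0, group: cVol}
  # mVol: micro volumes (2 ml)
  - {protocol_id: mVol_5_Gadoterate,   cm_type: Gadoterate,  cm_volume_ml: 2, flow_rate_ml_s: 5.0, group: mVol}
  - {protocol_id: mVol_5_Gadoteridol,  cm_type: Gadoteridol, cm_volume_ml: 2, flow_rate_ml_s: 5.0, group: mVol}
  - {protocol_id: mVol_1_Gadoterate,   cm_type: Gadoterate,  cm_volume_ml: 2, flow_rate_ml_s: 1.0, group: mVol}
  - {protocol_id: mVol_1_Gadoteridol,  cm_type: Gadoteridol, cm_volume_ml: 2, flow_rate_ml_s: 1.0, group: mVol}
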