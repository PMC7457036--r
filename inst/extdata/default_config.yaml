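# Default run configuration: synchronous control at 100 beats/min.
# All values are in mmHg-ml-s units.  Omitted fields fall back to these
# same defaults inside load_config(); an empty file is a valid config.
chambers:
  lv:
    Ees: 3.18        # maximal territory elastance (mmHg/ml), both territories
    V0: -15.0        # ESPVR volume intercept (ml); negative by design
    A: 12.8          # EDPVR scale (mmHg)
    B: 0.015         # EDPVR exponent (1/ml)
    Tmax: 0.2        # time to end systole (s)
    tau: 0.04        # relaxation time constant (s); calibration default
  la:
    Ees: 1.50
    V0: 5.0
    A: 0.044
    B: 0.049
    Tmax: 0.125
    tau: 0.08       # slow atrial relaxation sustains the kick into systole
  F: 0.5             # LAD-territory volume fraction of the LV
schedule:
  heart_rate: 100    # beats/min (T = 0.6 s)
  dt_lcx: 0.0        # LCX activation delay (s); or set SDI instead
  dt_bar: 0.0        # IMP clock delay (s)
  la_offset: 0.105   # atrial phase advance: kick centred just after onset
circulation:
  R_ao: 0.02
  R_per: 12.0
  R_ven: 0.05
  R_mv: 0.08
  C_art: 0.7
  C_ven: 15.0
  V_art0: 40.0
  V_ven0: 100.0
  R_lad: 1.5
  R_lcx: 3.0
imp:
  alpha: 0.8         # CEP weight on LV pressure
  beta: 5.0          # VE weight (ml)
  gamma: 20.0        # SIP scale (mmHg)
trees:
  lad:
    seed: 20         # synthetic 400-vessel tree (195 bif + 3 trif)
  lcx:
    seed: 21
init:
  V_la: 110.0
  V_lv: 50.0
  V_art: 90.0
  V_ven: 250.0
solver:
  rtol: 1.0e-6
  atol: 1.0e-8
  dt_out: 0.001      # output sampling (s)
  max_cycles: 50
  tol: 1.0e-3        # periodicity criterion (relative)
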