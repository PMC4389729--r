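# Complete default configuration for the MalonylSensor pipeline.
# Values here mirror defaultRunConfig(); a user config may state only
# the keys it overrides.
seed: 1
output_dir: malonyl-sensor-run
generator:
  constructs: [matCmatB, matCatoDA]
  iptg_mM: [0.01, 0.1, 0.3, 0.6, 1.0, 10.0]
  replicates: 3
  arabinose_pct: 0.01
  substrate: false
  sigma: 0.02          # relative measurement noise
  well_cv: 0.0         # clone-to-clone lognormal CV on vm
  n_times: 120         # readings per well
  Ts: 12.0             # minutes between readings
  growth:
    X0: 0.05           # OD600 after 20-fold dilution
    Xmax: 1.2          # carrying capacity (OD600)
    mu: 0.01           # 1/min (~70 min doubling)
    lag: 60.0          # minutes
  sensor:
    vm: 0.1            # uM/(OD*min), overridden per well by vm_map
    vg: 0.0            # growth-consumption term, off by default
    gammaM: 0.077      # 1/min (~13 min metabolite pole)
    kf: 1.0            # 1/(uM*min)
    kr: 2.4            # 1/min  => Kd = kr/kf = 2.4 uM
    fapR: 1.0          # uM
    kappa: 2.0         # a.u./(uM*min)
    gammaR: 0.003448   # 1/min (~290 min reporter pole)
  vm_map:
    basal: 0.005
    vmax: 0.1
    Kh: 0.3            # mM IPTG half-saturation
    n: 1.0
identification:
  order: 2             # reference model: 1 zero, 2 poles
analysis:
  od_threshold: 0.6    # log-phase anchor (OD600)
  od_floor: 0.05       # RFP/OD mask
  alpha: 0.05
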