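places:
- id: Sc
  kind: continuous
  initial_marking: 5.0
  label: sodium succinate (mM)
- id: Pyr
  kind: continuous
  initial_marking: 5.0
  label: sodium pyruvate (mM)
- id: CxI
  kind: generic
  initial_marking: 1.0
  label: ETC complex I
- id: CxII
  kind: generic
  initial_marking: 1.0
  label: ETC complex II
- id: CxIII
  kind: generic
  initial_marking: 1.0
  label: ETC complex III
- id: CxIV
  kind: generic
  initial_marking: 1.0
  label: ETC complex IV
- id: NOS
  kind: generic
  initial_marking: 1.0
  label: mitochondrial NO-synthase
- id: CsA
  kind: continuous
  initial_marking: 0.005
  label: cyclosporin A (mM)
- id: C1193
  kind: continuous
  initial_marking: 1.0e-05
  label: thiacalix[4]arene C-1193 (M)
- id: NADH
  kind: continuous
  initial_marking: 0.0
  label: NADH autofluorescence change (rel. units x1000)
  allow_negative: yes
- id: EP
  kind: continuous
  initial_marking: -40.0
  label: inner-membrane electric potential (mV)
  allow_negative: yes
- id: Ca_Fluo4
  kind: continuous
  initial_marking: 3.26
  label: matrix Ca2+, Fluo-4 fluorescence (rel. units x1000)
- id: NO_DAFFM
  kind: continuous
  initial_marking: 0.0
  label: NO, DAF-FM fluorescence (rel. units x1000)
- id: ROS_DCF
  kind: continuous
  initial_marking: 1000.0
  label: ROS, DCF fluorescence (rel. units x1000)
transitions:
- id: T_NADH_ctrl
  kind: continuous
  label: NADH production, control branch
  rate:
    coefficients:
    - -49.2
    - 14.88
    - -1.14
    valid_interval:
    - 0.0
    - 15.0
- id: T_NADH_c1193
  kind: continuous
  label: NADH production, c1193 branch
  rate:
    coefficients:
    - -30.8
    - 7.62
    - -0.48
    valid_interval:
    - 0.0
    - 15.0
- id: T_EP_ctrl
  kind: continuous
  label: EP production, control branch
  rate:
    coefficients:
    - -49.2
    - 14.88
    - -1.14
    valid_interval:
    - 0.0
    - 15.0
- id: T_EP_c1193
  kind: continuous
  label: EP production, c1193 branch
  rate:
    coefficients:
    - -30.8
    - 7.62
    - -0.48
    valid_interval:
    - 0.0
    - 15.0
- id: T_Ca_Fluo4_ctrl
  kind: continuous
  label: Ca_Fluo4 production, control branch
  rate:
    coefficients:
    - 106.15
    - -57.36
    - 12.18
    - -0.8
    valid_interval:
    - 0.0
    - 15.0
- id: T_Ca_Fluo4_c1193
  kind: continuous
  label: Ca_Fluo4 production, c1193 branch
  rate:
    coefficients:
    - 61.15
    - -39.16
    - 8.4
    - -0.56
    valid_interval:
    - 0.0
    - 15.0
- id: T_NO_DAFFM_ctrl
  kind: continuous
  label: NO_DAFFM production, control branch
  rate:
    coefficients:
    - 17.39
    valid_interval:
    - 0.0
    - 15.0
- id: T_NO_DAFFM_c1193
  kind: continuous
  label: NO_DAFFM production, c1193 branch
  rate:
    coefficients:
    - 13.12
    valid_interval:
    - 0.0
    - 15.0
- id: T_ROS_DCF_ctrl
  kind: continuous
  label: ROS_DCF production, control branch
  rate:
    coefficients:
    - 13.9
    valid_interval:
    - 0.0
    - 15.0
- id: T_ROS_DCF_c1193
  kind: continuous
  label: ROS_DCF production, c1193 branch
  rate:
    coefficients:
    - 1.3
    valid_interval:
    - 0.0
    - 15.0
- id: MPTP
  kind: discrete
  label: cyclosporin-sensitive permeability transition pore
  delay: 0.0
arcs:
- source: T_NADH_ctrl
  target: NADH
  kind: normal
  weight_or_threshold: 1.0
- source: C1193
  target: T_NADH_ctrl
  kind: inhibitory
  weight_or_threshold: 1.0e-09
- source: Sc
  target: T_NADH_ctrl
  kind: test
  weight_or_threshold: 0.1
- source: Pyr
  target: T_NADH_ctrl
  kind: test
  weight_or_threshold: 0.1
- source: CxI
  target: T_NADH_ctrl
  kind: test
  weight_or_threshold: 0.1
- source: T_NADH_c1193
  target: NADH
  kind: normal
  weight_or_threshold: 1.0
- source: C1193
  target: T_NADH_c1193
  kind: test
  weight_or_threshold: 1.0e-09
- source: Sc
  target: T_NADH_c1193
  kind: test
  weight_or_threshold: 0.1
- source: Pyr
  target: T_NADH_c1193
  kind: test
  weight_or_threshold: 0.1
- source: CxI
  target: T_NADH_c1193
  kind: test
  weight_or_threshold: 0.1
- source: T_EP_ctrl
  target: EP
  kind: normal
  weight_or_threshold: 1.0
- source: C1193
  target: T_EP_ctrl
  kind: inhibitory
  weight_or_threshold: 1.0e-09
- source: Sc
  target: T_EP_ctrl
  kind: test
  weight_or_threshold: 0.1
- source: Pyr
  target: T_EP_ctrl
  kind: test
  weight_or_threshold: 0.1
- source: CxI
  target: T_EP_ctrl
  kind: test
  weight_or_threshold: 0.1
- source: CxII
  target: T_EP_ctrl
  kind: test
  weight_or_threshold: 0.1
- source: CxIII
  target: T_EP_ctrl
  kind: test
  weight_or_threshold: 0.1
- source: CxIV
  target: T_EP_ctrl
  kind: test
  weight_or_threshold: 0.1
- source: T_EP_c1193
  target: EP
  kind: normal
  weight_or_threshold: 1.0
- source: C1193
  target: T_EP_c1193
  kind: test
  weight_or_threshold: 1.0e-09
- source: Sc
  target: T_EP_c1193
  kind: test
  weight_or_threshold: 0.1
- source: Pyr
  target: T_EP_c1193
  kind: test
  weight_or_threshold: 0.1
- source: CxI
  target: T_EP_c1193
  kind: test
  weight_or_threshold: 0.1
- source: CxII
  target: T_EP_c1193
  kind: test
  weight_or_threshold: 0.1
- source: CxIII
  target: T_EP_c1193
  kind: test
  weight_or_threshold: 0.1
- source: CxIV
  target: T_EP_c1193
  kind: test
  weight_or_threshold: 0.1
- source: T_Ca_Fluo4_ctrl
  target: Ca_Fluo4
  kind: normal
  weight_or_threshold: 1.0
- source: C1193
  target: T_Ca_Fluo4_ctrl
  kind: inhibitory
  weight_or_threshold: 1.0e-09
- source: Sc
  target: T_Ca_Fluo4_ctrl
  kind: test
  weight_or_threshold: 0.1
- source: Pyr
  target: T_Ca_Fluo4_ctrl
  kind: test
  weight_or_threshold: 0.1
- source: T_Ca_Fluo4_c1193
  target: Ca_Fluo4
  kind: normal
  weight_or_threshold: 1.0
- source: C1193
  target: T_Ca_Fluo4_c1193
  kind: test
  weight_or_threshold: 1.0e-09
- source: Sc
  target: T_Ca_Fluo4_c1193
  kind: test
  weight_or_threshold: 0.1
- source: Pyr
  target: T_Ca_Fluo4_c1193
  kind: test
  weight_or_threshold: 0.1
- source: T_NO_DAFFM_ctrl
  target: NO_DAFFM
  kind: normal
  weight_or_threshold: 1.0
- source: C1193
  target: T_NO_DAFFM_ctrl
  kind: inhibitory
  weight_or_threshold: 1.0e-09
- source: Sc
  target: T_NO_DAFFM_ctrl
  kind: test
  weight_or_threshold: 0.1
- source: Pyr
  target: T_NO_DAFFM_ctrl
  kind: test
  weight_or_threshold: 0.1
- source: NOS
  target: T_NO_DAFFM_ctrl
  kind: test
  weight_or_threshold: 0.1
- source: T_NO_DAFFM_c1193
  target: NO_DAFFM
  kind: normal
  weight_or_threshold: 1.0
- source: C1193
  target: T_NO_DAFFM_c1193
  kind: test
  weight_or_threshold: 1.0e-09
- source: Sc
  target: T_NO_DAFFM_c1193
  kind: test
  weight_or_threshold: 0.1
- source: Pyr
  target: T_NO_DAFFM_c1193
  kind: test
  weight_or_threshold: 0.1
- source: NOS
  target: T_NO_DAFFM_c1193
  kind: test
  weight_or_threshold: 0.1
- source: T_ROS_DCF_ctrl
  target: ROS_DCF
  kind: normal
  weight_or_threshold: 1.0
- source: C1193
  target: T_ROS_DCF_ctrl
  kind: inhibitory
  weight_or_threshold: 1.0e-09
- source: Sc
  target: T_ROS_DCF_ctrl
  kind: test
  weight_or_threshold: 0.1
- source: Pyr
  target: T_ROS_DCF_ctrl
  kind: test
  weight_or_threshold: 0.1
- source: CxIII
  target: T_ROS_DCF_ctrl
  kind: test
  weight_or_threshold: 0.1
- source: T_ROS_DCF_c1193
  target: ROS_DCF
  kind: normal
  weight_or_threshold: 1.0
- source: C1193
  target: T_ROS_DCF_c1193
  kind: test
  weight_or_threshold: 1.0e-09
- source: Sc
  target: T_ROS_DCF_c1193
  kind: test
  weight_or_threshold: 0.1
- source: Pyr
  target: T_ROS_DCF_c1193
  kind: test
  weight_or_threshold: 0.1
- source: CxIII
  target: T_ROS_DCF_c1193
  kind: test
  weight_or_threshold: 0.1
- source: Ca_Fluo4
  target: MPTP
  kind: test
  weight_or_threshold: 1000000.0
- source: CsA
  target: MPTP
  kind: inhibitory
  weight_or_threshold: 0.001
- source: Ca_Fluo4
  target: MPTP
  kind: normal
  weight_or_threshold: 1.0
metadata:
  condition: c1193
  c1193_concentration: 1.0e-05
  ca_model: quartic
  observables:
    NADH: NADH
    EP: EP
    Ca_Fluo4: Ca_Fluo4
    NO_DAFFM: NO_DAFFM
    ROS_DCF: ROS_DCF
    C1193: C1193
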