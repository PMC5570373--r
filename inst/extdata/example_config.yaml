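# Example configuration overrides; any subset of the spine_config() sections
# may appear here.  Values not listed keep the package defaults.
geometry:
  head_volume: 0.1        # um^3
  neck_length: 0.5        # um
glutamate:
  b_total: 0.5            # mM transporter concentration
  glu_rest: 0.25          # uM
  molecules_per_vesicle: 1500
receptors:
  counts:
    s_nr2a: 12
    s_nr2b: 8
    p_nr2b: 3
    e_nr2b: 8
    s_ampar: 85
    e_ampar_density: 20
electrics:
  r_neck: 157             # MOhm
  mg: 1.0                 # mM
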