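# Perturbation presets, one per reference in-silico experiment.
# enzyme_scales of -1 mark an upregulation whose factor is exposed as an
# argument of knockout_preset() (default 2).

identity:
  label: "no perturbation"

pip5ki_ko:
  label: "PIP5KI knockout"
  enzyme_scales: {PIP5KI: 0}

pi4k_ko:
  label: "PI4K knockout"
  enzyme_scales: {PI4K: 0}

complex_ko:
  label: "PI4K+PIP5KI+DVL complex-only knockout"
  enzyme_scales: {PI4K_PIP5KI_DVL: 0}

pip5kii_ko:
  label: "PIP5KII knockout"
  enzyme_scales: {PIP5KII: 0}

pi3ki_ko:
  label: "PI3KI knockout"
  enzyme_scales: {PI3KI: 0}

pi3kii_ko:
  label: "PI3KII knockout"
  enzyme_scales: {PI3KII: 0}

pikfyve_ko:
  label: "PIKfyve knockout"
  enzyme_scales: {PIKfyve: 0}

sioss_up:
  label: "SIOSS 5-phosphatases upregulated"
  upregulated: true
  enzyme_scales: {SIOSS: -1}

synj_tmem55_up:
  label: "SYNJ/TMEM55 4-phosphatases upregulated"
  upregulated: true
  enzyme_scales: {SYNJ_TMEM55: -1}

mtmr_65:
  label: "MTMR reduced to 65% (MTMR2 knockout surrogate)"
  enzyme_scales: {MTMR: 0.65}

pip5ki_half:
  label: "PIP5KI at 50% (complex follows)"
  enzyme_scales: {PIP5KI: 0.5}

pi4k_half:
  label: "PI4K at 50% (complex follows)"
  enzyme_scales: {PI4K: 0.5}

block_pip2_inputs:
  label: "all external inputs into PI(4)P and PI(4,5)P2 stopped; v0->4 at 20%"
  gamma_scales: {"v0->4": 0.2, "v0->45": 0, "v5->45": 0, "v345->45": 0, "v34->4": 0}
  influx_scales: {"v->4": 0}

apical:
  label: "apical membrane configuration (high PTEN, low PI3KI)"
  enzyme_values: {PTEN: 2.3e-15, PI3KI: 6.1e-16}

basolateral:
  label: "basolateral membrane configuration (low PTEN, high PI3KI)"
  enzyme_values: {PTEN: 3.9e-17, PI3KI: 1.5e-14}

v345_34_slow:
  label: "slow PI(3,4,5)P3 -> PI(3,4)P2 hydrolysis"
  gamma_values: {"v345->34": 1.0e+11}
  f_values: {"v345->34": 0.9982}

v345_34_fast:
  label: "fast PI(3,4,5)P3 -> PI(3,4)P2 hydrolysis (SHIP1-like)"
  gamma_values: {"v345->34": 6.0e+13}
  f_values: {"v345->34": 0.9998}

pten_kd_9833:
  label: "PTEN knockdown of 98.33%"
  enzyme_scales: {PTEN: 0.0167}

gamma0_half:
  label: "PI influx rate constant at 50%"
  influx_scales: {"v->0": 0.5}

gamma0_half_closed:
  label: "PI influx at 50%, PI(4)P and PI(3)P influxes closed"
  influx_scales: {"v->0": 0.5, "v->4": 0, "v->3": 0}

pi_drop_full:
  label: "PI influx at 2%, PI(4)P and PI(3)P influxes closed"
  influx_scales: {"v->0": 0.02, "v->4": 0, "v->3": 0}
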