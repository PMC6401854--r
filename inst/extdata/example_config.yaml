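# Example run configuration: valine-derived polymer under the standard
# synthetic-measurement conditions.
polymer: M-l-Val
seed: 42
titration:
  sample_conc: 0.05     # mol repeat units per L
  titrant_conc: 0.1     # mol/L NaOH
  ph_start: 1.7
  ph_end: 11.8
  ph_noise_sd: 0.02     # pH reading noise
cd:
  noise_sd: 0.02        # fraction of the positive-band amplitude
  pos_center: 234       # nm
n_units: 10
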