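# Detector preset for endolysosomal-reporter (Rab7) vesicles.
dot_pairs:
  - {scale: 4, cutoff: 0.5}
  - {scale: 2, cutoff: 0.08}
filament_pairs:
  - {scale: 2, cutoff: 1}
  - {scale: 1, cutoff: 0.9}
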