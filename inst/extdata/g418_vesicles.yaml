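# Detector preset for Texas-Red-labeled G418 puncta.
dot_pairs:
  - {scale: 4, cutoff: 0.04}
  - {scale: 1, cutoff: 0.05}
filament_pairs:
  - {scale: 3, cutoff: 0.2}
  - {scale: 2, cutoff: 0.09}
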