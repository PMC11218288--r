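# Synthetic virtual-patient configuration (ground truth for simulation;
# no real patient data). Mid-ability profile: shoulder axes limited to
# 70 degrees, full elbow flexion, strength around MMT grade 2.5.
patient:
  true_rom: {shoulder_azimuth: 70, shoulder_elevation: 70, elbow: 90}
  true_strength: 2.5
  aim_noise_sd: 0.06            # metres of endpoint scatter
  reaction_budget: 0.5          # seconds
  sweep_time: 2.0               # seconds to traverse the full required range
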