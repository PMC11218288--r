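# Therapist-entered clinical evaluation (example: the worked grade mix).
mmt_grades: [3, 3, 4]
rom:
  shoulder_azimuth: [0, 90]     # horizontal adduction/abduction, degrees
  shoulder_elevation: [0, 90]   # flexion, degrees
  elbow: [0, 90]                # flexion, degrees
brunnstrom_stage: IV
pain_score: 2
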