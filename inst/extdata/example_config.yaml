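# Engine configuration. Every field is optional; omitted values resolve
# to the documented defaults and are echoed in the resolved config.
dda:
  lower_hit_threshold: 0.50     # comfort-band floor (reduce below this)
  upper_hit_threshold: 0.70     # comfort-band ceiling (increase above)
  range_fraction_threshold: 0.70
steps:
  max_range_step: 10            # degrees per full-amplitude adjustment
  max_strength_step: 0.5        # MMT-grade units per full-amplitude adjustment
parameters:
  nominal_diameter: {III: 0.30, IV: 0.20, V: 0.12}   # metres
  nominal_speed: {III: 0.30, IV: 0.50, V: 0.75}      # metres/second
  round_duration: 30            # seconds
  spawn_interval: 3             # seconds between targets
  ascent_distance: 1.5          # metres a target climbs before vanishing
session:
  pain_threshold: 4             # stop training above this pain score
  bgm:
    per_miss_increase: 0.10
    compound: true
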