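# Design-document checklist example for `validate-design`: a game
# description that omits its assessment elements.
clinical:
  stage_goals: overall upper-limb motor training
  rehab_motion_features: shoulder and elbow movements, six preset levels
  # motor_function_evaluation: (not documented)
  # state_assessment_method: (not documented)
function:
  motion_mapping: shoulder, elbow, twist, trunk, hip, knee
  duration: per-round play with rest breaks
  game_rules: touch the target with the body within a limited time
  feedback: real-time joint display; hit/miss counts per round
  difficulty: six preset difficulty levels
interesting:
  reward_mechanism: score per touched target
  story: exercise scenarios
  art_design: 3D scenes
  music_sound_design: background music
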