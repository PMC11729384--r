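# Example pipeline configuration: a small synthetic run with moderate
# loadings (well identified at this sample size). Field reference:
# ?run_pipeline.
n: 1500
seed: 20260925
synthetic:
  latent_sds:
    screens: 0.3
    transport: 0.5
  loadings:
    screens: {computer_smartphone: 1, tv: 2, video_games: -3}
    transport: {motor_vehicle: 1, cycling: -2, walking: 0.8}
fit:
  quad: 9
  se: true
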