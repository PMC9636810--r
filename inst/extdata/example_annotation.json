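{
  "video_id": "example_3frames",
  "fps": 8,
  "pixel_pitch_mm": 0.0125,
  "frames": [
    {"idx": 0, "margin": [[100, 200], [180, 200]], "aca": [[12, 150], [300, 150]]},
    {"idx": 1, "margin": [[101, 200], [179, 200]], "aca": [[12.5, 150.2], [300.5, 150.2]]},
    {"idx": 2, "margin": [[102, 201], [178, 201]], "aca": [[13, 150.4], [301, 150.4]]}
  ]
}
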