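{
  "parameter_set": "heart",
  "environment": {"delta_psi": 190, "temperature": 298},
  "protocol": {
    "pulse_height": 209,
    "pulse_duration": 5,
    "prepulse_height": 50,
    "interpulse_height": 98,
    "interpulse_duration": 30,
    "n_pulses": 2,
    "postpulse_duration": 10
  },
  "seed": 7
}
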