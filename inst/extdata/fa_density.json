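{
  "60": 1.131,
  "70": 1.153,
  "80": 1.174,
  "90": 1.192
}
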