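{
  "glucan": 0.434,
  "xylan": 0.244,
  "arabinan": 0.012,
  "acetyl": 0.0251,
  "klason_lignin": 0.242,
  "acid_soluble_lignin": 0.0288
}
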