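{
  "cin": 1907,
  "negative": 4790,
  "concordant_normal": 63209
}
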