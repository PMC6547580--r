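{
  "NDC80": "KNTC2",
  "NUF2": "CDCA1",
  "ORC6": "ORC6L"
}
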