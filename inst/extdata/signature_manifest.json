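{
  "signature_hypo_up.tsv": "4cab4ef8c1714f101e6d9569a88a6a30ba2622a341719a902d8fa20941a25ec3",
  "signature_hyper_down.tsv": "56a483bce83e99f5e0b8c4bab22c09999485f2f3890c3f0f5bdff10370b0d38e"
}
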