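{
  "0": "Nervous disease",
  "1": "Gynecology",
  "2": "Mental illness",
  "3": "Eye disease",
  "4": "Ear disease and disorders",
  "5": "Internal disease",
  "6": "Chronic disease",
  "7": "Skin disease",
  "8": "Orthopedic conditions",
  "9": "Dental disease"
}
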