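groups:
  cereals: 25.98
  fats and oils: 12.82
  milk and dairy products: 8.85
  sugars, sweets and pastries: 2.93
  beverages: 2.04
  meat and meat products: 5.45
  fruits and nuts: 13.13
  eggs: 2.42
  fish: 8.07
  legumes: 11.62
  vegetables: 4.64
  miscellaneous: 2.06
tolerance: 3.0
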