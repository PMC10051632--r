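chfb:
  breaks:
  - 10.0
  - 12.0
  - 14.0
  - 16.0
  - 18.0
sfa:
  breaks:
  - 10.0
  - 12.0
  - 14.0
  - 16.0
  - 18.0
sodium:
  breaks:
  - 2000.0
  - 2300.0
  - 2600.0
  - 2900.0
  - 3200.0
fiber:
  breaks:
  - 5.0
  - 10.0
  - 15.0
  - 20.0
  - 25.0
protein:
- min: 0.0
  max: 0.6
  min_closed: yes
  max_closed: no
  points: 0
- min: 0.6
  max: 0.83
  min_closed: yes
  max_closed: no
  points: 2
- min: 0.83
  max: 1.0
  min_closed: yes
  max_closed: yes
  points: 5
- min: 1.0
  max: 1.2
  min_closed: no
  max_closed: yes
  points: 4
- min: 1.2
  max: 1.4
  min_closed: no
  max_closed: yes
  points: 3
- min: 1.4
  max: 1.6
  min_closed: no
  max_closed: yes
  points: 2
- min: 1.6
  max: 1.8
  min_closed: no
  max_closed: yes
  points: 1
- min: 1.8
  max: '.inf'
  min_closed: no
  max_closed: yes
  points: 0
bmdp:
  lower: 0.33
  upper: 0.77
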