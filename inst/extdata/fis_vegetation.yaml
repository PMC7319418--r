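resolution: 0.01
and_operator: min
aggregation: max
defuzzifier: centroid
antecedents:
- name: streamside_bfi
  universe:
  - 0.0
  - 5.0
  mfs:
    unsuitable:
    - 0.0
    - 0.0
    - 0.5
    - 1.0
    barely:
    - 0.5
    - 1.0
    - 1.5
    - 2.0
    moderately:
    - 1.5
    - 2.0
    - 2.5
    - 3.0
    suitable:
    - 2.5
    - 3.0
    - 3.5
    - 4.0
    preferred:
    - 3.5
    - 4.0
    - 5.0
    - 5.0
- name: riparian_bfi
  universe:
  - 0.0
  - 5.0
  mfs:
    unsuitable:
    - 0.0
    - 0.0
    - 0.5
    - 1.0
    barely:
    - 0.5
    - 1.0
    - 1.5
    - 2.0
    moderately:
    - 1.5
    - 2.0
    - 2.5
    - 3.0
    suitable:
    - 2.5
    - 3.0
    - 3.5
    - 4.0
    preferred:
    - 3.5
    - 4.0
    - 5.0
    - 5.0
consequent:
  name: veg_capacity
  universe:
  - 0.0
  - 30.0
  mfs:
    none:
    - 0.0
    - 0.0
    - 0.1
    - 0.5
    rare:
    - 0.1
    - 0.5
    - 1.0
    - 1.5
    occasional:
    - 1.0
    - 1.5
    - 4.0
    - 5.0
    frequent:
    - 4.0
    - 5.0
    - 12.0
    - 15.0
    pervasive:
    - 12.0
    - 15.0
    - 30.0
    - 30.0
rules:
- - unsuitable
  - unsuitable
  - none
- - unsuitable
  - barely
  - none
- - unsuitable
  - moderately
  - rare
- - unsuitable
  - suitable
  - rare
- - unsuitable
  - preferred
  - occasional
- - barely
  - unsuitable
  - rare
- - barely
  - barely
  - rare
- - barely
  - moderately
  - rare
- - barely
  - suitable
  - occasional
- - barely
  - preferred
  - occasional
- - moderately
  - unsuitable
  - rare
- - moderately
  - barely
  - occasional
- - moderately
  - moderately
  - occasional
- - moderately
  - suitable
  - occasional
- - moderately
  - preferred
  - frequent
- - suitable
  - unsuitable
  - occasional
- - suitable
  - barely
  - occasional
- - suitable
  - moderately
  - frequent
- - suitable
  - suitable
  - frequent
- - suitable
  - preferred
  - frequent
- - preferred
  - unsuitable
  - occasional
- - preferred
  - barely
  - frequent
- - preferred
  - moderately
  - frequent
- - preferred
  - suitable
  - pervasive
- - preferred
  - preferred
  - pervasive
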