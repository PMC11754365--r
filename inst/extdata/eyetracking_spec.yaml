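# Twelve marginal probabilities of the 5x5x5 gaze table: pXY_ fixes the
# first two factors and sums the third; pX_Y fixes the first and third.
dims: [5, 5, 5]
patterns:
  - [1, 1, _]
  - [1, _, 1]
  - [2, 2, _]
  - [2, _, 2]
  - [3, 3, _]
  - [3, _, 3]
  - [3, 4, _]
  - [3, _, 4]
  - [4, 3, _]
  - [4, _, 3]
  - [4, 4, _]
  - [4, _, 4]
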