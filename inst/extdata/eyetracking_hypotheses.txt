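# Interaction (H1, H2) and no-interaction (H3, H4) hypotheses on the twelve
# marginal probabilities of the 5x5x5 gaze table. pXY_ = sum over the third
# factor at levels (X, Y) of the first two; pX_Y = sum over the second factor.
H1: p11_ > p1_1; p22_ > p2_2; p33_ > p3_3; p44_ > p4_4
H2: p11_ > p1_1; p22_ > p2_2; p34_ > p3_4; p43_ > p4_3
H3: p11_ = p1_1; p22_ = p2_2; p33_ = p3_3; p44_ = p4_4
H4: p11_ = p1_1; p22_ = p2_2; p34_ = p3_4; p43_ = p4_3
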