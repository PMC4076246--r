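# Worked example, panel A: classic confounding.
# W may cause both exposure X and outcome Y; U_X, U_Y, U_W are independent
# exogenous causes. Sufficient adjustment set: {W}.
W -> X
W -> Y
X -> Y
U_X -> X
U_Y -> Y
U_W -> W
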