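# Worked example, panel B: collider.
# X and Y both cause W; conditioning on the collider W opens the path
# X - W - Y. Sufficient adjustment set: {} (adjust for nothing).
X -> W
Y -> W
X -> Y
U_X -> X
U_Y -> Y
U_W -> W
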