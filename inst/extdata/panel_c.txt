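# Worked example, panel C: adjusting for W3 alone opens a new biasing
# path through W1 and W2 (W3 is a collider on X <- W1 -> W3 <- W2 -> Y).
# Minimal sufficient adjustment sets: {W1, W3} and {W2, W3}.
# The wiring below is a canonical reconstruction consistent with those
# facts; the original figure is not machine-readable.
W1 -> X
W3 -> X
X -> Y
W3 -> Y
W2 -> Y
W1 -> W3
W2 -> W3
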