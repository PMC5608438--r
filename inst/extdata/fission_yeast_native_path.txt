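# Ten-state biological cell-cycle path of the fission yeast network.
# One state per line: bits in node order (CS SK Cdc2/Cdc13 Ste9 Rum1 Slp1
# Cdc2/Cdc13* Wee1/Mik1 Cdc25 PP), then the phase label.
1 0 0 1 1 0 0 1 0 0 START
0 1 0 1 1 0 0 1 0 0 G1
0 0 0 0 0 0 0 1 0 0 G1/S
0 0 1 0 0 0 0 1 0 0 G2
0 0 1 0 0 0 0 0 1 0 G2
0 0 1 0 0 0 1 0 1 0 G2/M
0 0 1 0 0 1 1 0 1 0 G2/M
0 0 0 0 0 1 0 0 1 1 M
0 0 0 1 1 0 0 1 0 1 M
0 0 0 1 1 0 0 1 0 0 G1/G0
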