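# Two-layer circuit computing the elementary CA transition rules 110 and
# 124 jointly: two 2-input ORs and a 3-input NAND (shared by both outputs,
# i.e. fan-out 2) feeding two 2-input ANDs.
input L
input C
input R
gate OR1 = OR(C, R)
gate OR2 = OR(C, L)
gate NAND1 = NAND(L, C, R)
gate AND1 = AND(OR1, NAND1)
gate AND2 = AND(OR2, NAND1)
output R110 = AND1
output R124 = AND2
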