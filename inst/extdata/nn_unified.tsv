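# Unified nearest-neighbor parameters for DNA/DNA duplexes, 1 M NaCl.
# dH in kcal/mol, dS in cal/(mol K).
# Source: SantaLucia J Jr (1998) PNAS 95:1460-1465, Table 1 (unified set);
# initiation terms per terminal base pair; sym applies to self-complementary duplexes.
# Key XY/ZW denotes 5'-XY-3' stacked on 3'-ZW-5'.
key	dH	dS
AA/TT	-7.9	-22.2
AT/TA	-7.2	-20.4
TA/AT	-7.2	-21.3
CA/GT	-8.5	-22.7
GT/CA	-8.4	-22.4
CT/GA	-7.8	-21.0
GA/CT	-8.2	-22.2
CG/GC	-10.6	-27.2
GC/CG	-9.8	-24.4
GG/CC	-8.0	-19.9
init_A/T	2.3	4.1
init_G/C	0.1	-2.8
sym	0.0	-1.4
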