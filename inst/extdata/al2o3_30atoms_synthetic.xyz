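30
synthetic Al2O3 cluster, 18 O / 12 Al (idealised lattice cutout, not a relaxed structure)
O 0.000000 -2.100000 -4.200000
O -2.100000 0.000000 -4.200000
O 2.100000 0.000000 -4.200000
O 0.000000 2.100000 -4.200000
O -2.100000 -2.100000 -2.100000
Al 0.000000 -2.100000 -2.100000
O 2.100000 -2.100000 -2.100000
Al -2.100000 0.000000 -2.100000
O 0.000000 0.000000 -2.100000
Al 2.100000 0.000000 -2.100000
O -2.100000 2.100000 -2.100000
Al 0.000000 2.100000 -2.100000
O 2.100000 2.100000 -2.100000
O 0.000000 -2.100000 0.000000
Al -4.200000 0.000000 0.000000
O -2.100000 0.000000 0.000000
O 2.100000 0.000000 0.000000
Al -2.100000 2.100000 0.000000
O 0.000000 2.100000 0.000000
Al 0.000000 4.200000 0.000000
O -2.100000 -2.100000 2.100000
Al 0.000000 -2.100000 2.100000
O 2.100000 -2.100000 2.100000
Al -2.100000 0.000000 2.100000
O 0.000000 0.000000 2.100000
Al 2.100000 0.000000 2.100000
O -2.100000 2.100000 2.100000
Al 0.000000 2.100000 2.100000
O 2.100000 2.100000 2.100000
Al 0.000000 0.000000 4.200000
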