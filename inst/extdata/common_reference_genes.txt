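# 14 commonly used Arabidopsis reference genes (TAIR IDs)
# ACT2, ACT7, ACT8, APT1, EF1a, eIF4A, NDUFA8, TUB2, TUB6, TUB9,
# UBQ4, UBQ5, UBQ10, UBQ11
AT3G18780
AT5G09810
AT1G49240
AT1G27450
AT5G60390
AT3G13920
AT5G18800
AT5G62690
AT5G12250
AT4G20890
AT5G20620
AT3G62250
AT4G05320
AT4G05050
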