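class	copies_raw	bp_raw	copies_final	bp_final
SINE	42694	463447	1466	182635
LINE	127084	35233072	61906	19307025
LTR	82330	43924839	45188	33395659
DNA	4279	1160803	965	483169
Unclassified	487	204826	NA	NA
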