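# synthetic demo: residues flagged as distinguished
A:5
A:6
A:11
A:14
A:15
A:17
A:21
A:42
A:46
A:49
A:55
A:56
A:61
A:68
A:71
A:77
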