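area,V1,V2,V4,LAT
V1,0,1,0.1,0.01
V2,1,0,1,0.1
V4,0.1,1,0,1
LAT,0.01,0.1,1,0
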