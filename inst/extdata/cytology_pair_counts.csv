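grade,NILM,ASC-US,ASC-H,LSIL,HSIL
NILM,63233,513,45,20,0
ASC-US,2569,20883,235,246,0
ASC-H,0,18,1227,89,97
LSIL,0,867,271,7062,238
HSIL,0,0,21,16,899
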