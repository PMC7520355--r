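histology,arm,grade,count
cervicitis,ai,NILM,23
cervicitis,ai,ASC-US,1889
cervicitis,ai,ASC-H,330
cervicitis,ai,LSIL,2407
cervicitis,ai,HSIL,141
cervicitis,manual,NILM,217
cervicitis,manual,ASC-US,1900
cervicitis,manual,ASC-H,387
cervicitis,manual,LSIL,2068
cervicitis,manual,HSIL,218
CIN1,ai,NILM,0
CIN1,ai,ASC-US,104
CIN1,ai,ASC-H,62
CIN1,ai,LSIL,598
CIN1,ai,HSIL,55
CIN1,manual,NILM,14
CIN1,manual,ASC-US,156
CIN1,manual,ASC-H,73
CIN1,manual,LSIL,503
CIN1,manual,HSIL,73
CIN2,ai,NILM,0
CIN2,ai,ASC-US,34
CIN2,ai,ASC-H,43
CIN2,ai,LSIL,171
CIN2,ai,HSIL,31
CIN2,manual,NILM,7
CIN2,manual,ASC-US,54
CIN2,manual,ASC-H,43
CIN2,manual,LSIL,141
CIN2,manual,HSIL,34
CIN3,ai,NILM,1
CIN3,ai,ASC-US,65
CIN3,ai,ASC-H,144
CIN3,ai,LSIL,337
CIN3,ai,HSIL,180
CIN3,manual,NILM,13
CIN3,manual,ASC-US,85
CIN3,manual,ASC-H,139
CIN3,manual,LSIL,303
CIN3,manual,HSIL,187
cancer,ai,NILM,0
cancer,ai,ASC-US,8
cancer,ai,ASC-H,20
cancer,ai,LSIL,29
cancer,ai,HSIL,25
cancer,manual,NILM,3
cancer,manual,ASC-US,9
cancer,manual,ASC-H,18
cancer,manual,LSIL,25
cancer,manual,HSIL,27
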