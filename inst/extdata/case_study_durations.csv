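test,subject,method_a,method_b
STEET,1,43,32
STEET,2,56,59
STEET,3,59,108
STEET,4,121,123
STEET,5,104,99
STEET,6,48,60
STEET,7,98,105
STEET,8,123,117
STEET,9,59,52
STEET,10,75,85
TCSET,1,42,66
TCSET,2,79,74
TCSET,3,107,148
TCSET,4,112,99
TCSET,5,101,89
TCSET,6,79,59
TCSET,7,118,94
TCSET,8,78,79
TCSET,9,77,71
TCSET,10,154,144
SBET_RIGHT,1,30,25
SBET_RIGHT,2,31,20
SBET_RIGHT,3,51,69
SBET_RIGHT,4,38,44
SBET_RIGHT,5,33,38
SBET_RIGHT,6,34,36
SBET_RIGHT,7,52,52
SBET_RIGHT,8,55,46
SBET_RIGHT,9,21,17
SBET_RIGHT,10,39,62
SBET_LEFT,1,26,29
SBET_LEFT,2,28,30
SBET_LEFT,3,54,72
SBET_LEFT,4,46,52
SBET_LEFT,5,35,32
SBET_LEFT,6,30,34
SBET_LEFT,7,35,39
SBET_LEFT,8,46,45
SBET_LEFT,9,28,18
SBET_LEFT,10,25,55
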