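line,treatment,period,cases,evaluable
G11,C,1,0,35
G11,C,2,0,33
G11,C,3,0,24
G11,C,4,4,31
G11,C,5,8,28
G11,C,6,10,28
G11,C,7,10,23
G11,E,1,0,11
G11,E,2,0,12
G11,E,3,1,10
G11,E,4,3,11
G11,E,5,6,12
G11,E,6,6,10
G11,E,7,1,3
G11,S,1,0,37
G11,S,2,0,27
G11,S,3,0,28
G11,S,4,0,3
G11,S,5,0,3
G11,S,6,0,0
G11,S,7,0,0
G11,SE,1,0,12
G11,SE,2,0,10
G11,SE,3,0,11
G11,SE,4,0,5
G11,SE,5,0,2
G11,SE,6,1,4
G11,SE,7,0,3
WLA,C,1,0,38
WLA,C,2,0,36
WLA,C,3,0,36
WLA,C,4,15,33
WLA,C,5,23,36
WLA,C,6,26,35
WLA,C,7,20,26
WLA,E,1,0,12
WLA,E,2,0,12
WLA,E,3,0,12
WLA,E,4,3,11
WLA,E,5,6,11
WLA,E,6,7,11
WLA,E,7,5,8
WLA,S,1,0,36
WLA,S,2,0,30
WLA,S,3,1,35
WLA,S,4,1,12
WLA,S,5,0,9
WLA,S,6,0,9
WLA,S,7,0,8
WLA,SE,1,0,11
WLA,SE,2,0,12
WLA,SE,3,0,11
WLA,SE,4,0,10
WLA,SE,5,0,10
WLA,SE,6,0,8
WLA,SE,7,0,9
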