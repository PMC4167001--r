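cell,C,gL,EL,DeltaT,tauw,b,Vr,VT
L3,125.3,6.0,-74.6,3.5,229.8,37.9,-96.0,-57.7
L5,246.2,6.9,-71.7,3.0,263.7,25.1,-76.4,-60.1
FS,48.4,4.3,-75.5,3.1,25.4,66.5,-98.5,-64.1
BT,80.5,4.3,-79.2,2.7,74.3,30.3,-95.6,-71.9
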