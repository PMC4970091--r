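seedling,internode,observed_mm,estimated_mm
A,1-2,29.6,33.1
A,2-3,47.2,49.2
A,3-4,24.3,27.7
A,All,34.6,37.5
B,1-2,25.0,25.1
B,2-3,33.2,46.0
B,3-4,55.3,49.8
B,All,30.5,35.2
C,1-2,23.2,22.7
C,2-3,39.6,40.1
C,3-4,35.0,40.0
C,4-5,48.5,49.1
C,All,33.1,34.2
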