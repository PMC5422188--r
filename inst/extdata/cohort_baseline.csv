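patient,gender,hy_on,hy_off,age,updrs3_off,updrs3_on
1,male,2.5,3,62,5,10
2,male,2.5,3,69,18,27
3,male,2,3,70,7,24
4,male,2.5,3,54,21,35
5,male,2.5,3,61,8,40
6,female,2,3,59,11,20
7,male,2.5,3,76,42,45
8,female,2.5,3,71,11,24
9,female,2.5,3,66,4,12
10,male,2.5,3,66,24,35
11,male,2,2.5,61,17,32
12,female,2.5,3,71,6,17
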