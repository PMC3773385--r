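trial,grade_I,grade_II,grade_III,overall,n_features
1,100,83.3,87.5,90.0,3
2,100,83.3,75.0,85.0,2
3,100,100.0,87.5,95.0,2
4,100,83.3,87.5,90.0,3
5,100,66.7,87.5,85.0,3
6,100,50.0,100,85.0,3
7,100,100,87.5,95.0,3
8,100,100,75.0,90.0,2
9,100,83.3,75.0,85.0,3
10,100,83.3,100,95.0,3
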