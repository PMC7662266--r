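participant,expected_average_error_pct,true_class,normal,unstable_left,unstable_right,supination,pronation
3,25.4,normal,132,35,11,0,0
3,25.4,unstable_left,37,21,0,0,2
3,25.4,unstable_right,19,0,37,0,0
3,25.4,supination,17,0,0,38,0
3,25.4,pronation,0,3,0,0,50
8,19.0,normal,123,5,2,3,10
8,19.0,unstable_left,23,23,0,1,0
8,19.0,unstable_right,1,6,42,1,0
8,19.0,supination,1,3,0,46,0
8,19.0,pronation,8,0,0,1,40
13,0.9,normal,140,1,0,1,0
13,0.9,unstable_left,0,54,0,0,0
13,0.9,unstable_right,0,0,52,0,0
13,0.9,supination,0,0,0,52,0
13,0.9,pronation,1,0,0,0,56
15,32.3,normal,111,9,0,9,0
15,32.3,unstable_left,0,13,30,0,6
15,32.3,unstable_right,0,0,49,0,0
15,32.3,supination,15,3,0,22,0
15,32.3,pronation,1,2,0,0,14
18,0.8,normal,130,0,0,0,0
18,0.8,unstable_left,1,53,0,0,0
18,0.8,unstable_right,2,1,54,0,0
18,0.8,supination,0,0,0,52,0
18,0.8,pronation,0,0,0,0,56
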