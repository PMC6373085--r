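age_band,sex,count
0-4,male,870
0-4,female,830
5-9,male,925
5-9,female,880
10-14,male,1050
10-14,female,1000
15-19,male,1090
15-19,female,1040
20-24,male,1090
20-24,female,1060
25-29,male,1060
25-29,female,1060
30-34,male,1060
30-34,female,1080
35-39,male,1130
35-39,female,1150
40-44,male,1310
40-44,female,1330
45-49,male,1290
45-49,female,1320
50-54,male,1170
50-54,female,1200
55-59,male,1050
55-59,female,1080
60-64,male,800
60-64,female,830
65-69,male,600
65-69,female,650
70-74,male,490
70-74,female,560
75-79,male,400
75-79,female,500
80-84,male,250
80-84,female,380
85+,male,150
85+,female,340
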