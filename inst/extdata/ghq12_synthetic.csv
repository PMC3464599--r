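concentrate,useful,decisions,enjoy,face_problems,happy,lost_sleep,strain,overcome,unhappy,confidence_loss,worthless
4,4,3,4,3,2,4,4,4,4,4,3
4,4,4,2,3,3,4,4,3,4,3,3
3,2,2,1,1,1,3,2,2,3,2,1
4,3,2,3,1,1,4,3,4,4,2,3
4,4,3,3,2,3,4,4,3,4,2,3
4,3,4,3,2,3,3,3,3,3,2,1
4,NA,4,3,3,3,4,3,2,2,1,3
2,4,3,2,1,2,4,3,4,3,2,3
3,3,2,2,1,1,4,2,2,1,1,1
2,1,2,2,1,1,4,4,3,3,3,2
4,1,2,1,1,1,4,4,4,3,3,2
2,2,2,2,1,1,4,2,3,3,3,3
3,3,2,1,1,1,4,2,3,3,1,1
4,4,3,4,4,2,3,1,1,1,2,1
4,4,4,4,4,4,4,3,2,2,2,2
4,3,2,3,3,1,4,4,4,4,3,2
3,2,2,1,1,1,3,2,3,3,2,1
4,4,2,3,1,3,4,3,3,1,1,2
4,4,4,3,3,3,2,2,1,1,1,1
3,1,2,2,2,2,4,2,3,3,1,2
2,3,3,4,2,2,2,3,2,1,1,1
3,4,4,3,2,2,4,4,3,2,2,1
1,4,1,1,1,1,1,1,3,1,1,1
3,4,3,3,2,1,3,3,3,3,1,1
4,3,4,2,1,3,4,3,3,2,2,4
4,4,4,3,4,3,4,4,4,4,3,2
4,2,4,3,2,1,3,2,4,4,4,3
2,1,1,1,1,1,2,2,4,3,1,2
4,3,3,2,3,1,4,4,4,3,4,2
4,4,4,4,2,3,3,3,2,2,2,1
3,3,2,3,1,1,4,3,NA,3,1,1
2,2,3,3,1,1,4,4,4,4,4,4
4,4,4,4,2,2,3,1,2,1,1,1
4,3,3,3,3,1,3,4,2,2,2,1
4,4,2,2,1,1,1,2,1,3,1,1
3,2,4,3,2,1,1,2,1,1,1,1
2,3,1,1,1,1,4,4,4,4,3,3
4,4,4,3,3,3,4,4,4,3,4,2
4,4,2,4,3,4,2,1,2,1,1,1
4,1,2,1,1,1,4,1,3,3,3,1
3,2,3,1,2,1,1,1,1,1,1,1
4,2,4,1,1,2,3,3,2,1,2,3
2,2,1,1,1,1,2,1,1,1,1,1
3,2,1,1,1,1,3,1,2,1,1,1
4,3,4,3,3,1,2,2,2,1,2,2
3,3,1,3,1,1,4,3,2,2,1,1
3,3,1,3,1,1,4,3,2,1,2,1
2,3,3,2,2,2,1,2,2,1,1,1
3,3,2,1,1,2,4,3,3,3,1,2
4,3,4,3,4,4,4,3,3,2,2,3
3,3,3,1,2,1,4,3,4,2,4,3
3,4,1,2,2,1,2,2,1,1,1,1
4,3,2,3,3,2,3,3,4,2,3,1
1,2,3,3,1,1,3,1,2,1,1,1
3,3,2,3,2,2,3,3,4,2,2,2
3,4,3,3,3,2,4,4,2,1,2,2
1,1,2,1,1,1,2,2,1,1,2,1
4,3,1,1,2,3,2,2,2,1,1,1
4,4,2,3,2,2,3,3,1,1,1,1
4,3,3,2,3,3,4,4,3,3,3,3
3,4,1,3,2,2,3,2,3,2,1,2
4,3,2,2,1,2,3,4,3,2,2,1
1,1,1,1,1,1,3,4,2,3,3,1
4,3,3,2,3,1,4,3,4,2,3,1
4,2,2,1,1,1,3,3,1,1,1,1
4,4,4,4,4,3,4,4,4,4,3,4
3,3,2,2,1,1,4,3,1,2,1,1
3,3,4,3,2,3,4,3,3,2,2,2
2,3,2,3,1,1,2,1,3,2,2,1
4,4,4,2,2,2,2,2,1,1,3,1
4,3,2,2,1,2,3,3,3,1,1,1
4,3,4,2,3,1,3,4,2,2,1,1
4,4,4,2,2,1,3,3,3,3,1,1
3,2,2,1,2,1,4,3,1,1,3,2
4,4,3,3,2,1,3,4,3,1,2,1
3,3,2,1,1,1,4,3,3,1,1,1
4,4,3,2,2,2,2,4,3,2,3,1
4,3,3,4,4,3,1,1,1,1,1,1
2,2,2,1,1,1,4,4,4,3,4,1
4,4,3,3,4,1,4,3,2,2,2,2
3,4,3,2,1,2,3,4,2,3,3,2
4,4,4,4,4,2,1,1,2,1,1,2
3,1,1,1,1,1,4,4,4,4,3,3
4,3,2,2,1,1,4,1,3,1,2,3
2,1,2,2,1,1,4,4,4,4,4,4
1,1,1,1,1,1,4,4,3,3,2,2
3,2,2,2,2,2,4,4,3,3,1,2
3,3,1,2,NA,1,1,2,1,1,1,1
2,3,1,1,1,1,4,3,2,1,1,1
4,4,4,3,4,3,4,2,3,3,2,1
4,3,4,2,1,2,3,3,4,2,1,3
2,1,1,1,1,1,3,3,3,2,1,1
4,4,4,4,3,3,3,1,2,2,2,2
4,4,4,2,4,2,2,2,3,1,1,1
4,4,3,3,2,4,4,3,3,2,2,2
4,4,3,3,3,2,4,3,2,3,3,2
4,4,4,3,2,1,3,3,3,1,1,1
4,3,4,2,3,3,3,2,3,3,2,2
2,2,2,2,1,1,3,4,3,2,2,3
4,4,3,2,2,1,1,3,1,1,1,1
4,3,4,2,2,1,4,2,3,2,2,1
3,2,2,2,2,1,3,4,3,2,1,1
4,4,4,3,4,3,4,2,3,3,1,2
3,1,1,1,1,1,3,3,2,2,1,1
3,2,1,2,2,1,4,4,4,3,3,4
1,1,1,1,1,1,4,4,4,2,3,2
2,3,4,4,3,1,4,2,3,2,1,1
4,4,4,3,3,3,4,4,3,2,3,2
3,1,3,2,1,1,3,4,2,3,2,1
3,2,3,2,2,2,3,3,3,2,2,1
4,4,4,4,3,3,2,2,1,1,1,1
3,4,2,1,1,1,4,4,2,4,2,1
2,3,3,2,1,2,2,3,3,2,1,1
4,4,4,3,3,1,2,2,1,2,1,1
4,3,3,4,3,2,3,3,3,1,1,1
4,2,4,1,1,1,3,4,2,2,1,2
3,2,2,1,2,1,4,4,4,3,4,3
3,1,4,1,1,1,3,3,3,3,1,2
3,3,3,1,1,2,4,4,3,4,3,4
3,2,3,1,1,1,4,3,3,4,NA,2
4,4,3,3,1,2,2,1,2,1,1,1
4,2,1,2,1,2,3,3,1,2,1,1
2,1,1,1,1,1,1,1,3,1,3,1
4,4,4,2,1,1,3,4,3,2,3,1
1,1,1,1,1,1,4,3,3,4,2,1
4,4,4,3,3,2,1,2,1,3,4,1
1,1,1,1,1,1,1,4,2,2,1,3
3,2,3,1,2,2,2,3,4,4,2,2
2,4,1,2,1,1,4,3,2,1,2,1
1,1,1,1,1,1,4,3,3,2,3,1
4,4,3,4,3,1,2,4,2,2,4,1
4,3,3,3,2,1,3,3,1,2,2,1
4,4,2,2,1,1,4,4,3,3,2,3
3,2,3,3,2,2,2,1,1,1,1,1
3,3,2,2,2,1,4,4,3,3,2,2
4,3,3,1,2,2,3,1,1,1,1,1
4,3,2,2,2,1,4,3,2,2,2,1
2,3,1,1,1,1,4,3,3,2,1,1
1,1,1,3,1,1,3,4,2,3,1,2
2,3,2,1,2,2,4,2,1,2,1,1
1,1,1,1,1,1,3,2,1,2,1,1
1,1,1,1,1,1,4,3,1,1,2,1
4,4,4,4,4,4,4,3,4,3,3,1
3,3,1,3,2,1,4,4,4,4,4,3
4,2,3,2,4,2,4,3,4,2,1,3
3,1,2,1,1,1,4,3,3,3,3,1
4,4,3,4,4,2,4,3,4,3,2,1
2,4,3,1,2,3,4,3,3,2,3,2
4,4,4,3,2,1,3,2,1,3,3,1
4,4,4,2,3,2,3,3,1,1,1,1
4,3,1,1,2,2,4,3,4,2,3,2
2,2,1,3,1,1,4,4,4,3,2,2
1,2,2,1,1,1,4,3,3,3,2,1
4,2,3,2,1,3,4,4,4,3,3,3
4,1,2,2,1,1,2,4,2,2,2,2
4,4,3,4,3,3,3,2,1,2,2,1
4,4,3,4,3,1,4,3,3,3,4,3
3,2,2,1,2,1,3,1,1,1,1,1
1,3,1,1,1,1,3,2,4,3,1,2
4,3,3,1,2,2,2,3,1,3,1,2
3,3,4,3,2,1,3,4,3,2,2,3
3,3,3,3,2,2,4,4,4,4,4,2
4,4,4,4,4,3,2,4,3,1,2,2
2,2,1,1,1,1,3,4,2,3,1,1
2,2,1,2,2,1,4,2,3,1,1,1
2,3,3,3,2,1,3,2,3,1,3,1
4,3,2,2,3,1,4,3,2,2,1,1
4,3,3,2,3,2,4,3,3,2,1,2
3,4,3,4,4,2,4,4,2,3,2,3
4,3,3,4,3,3,3,2,2,2,1,1
4,3,1,3,2,2,4,4,3,2,3,2
4,4,4,3,4,3,3,3,3,4,2,1
3,2,2,1,1,1,4,3,1,2,1,2
2,3,3,1,1,2,2,4,4,1,1,2
3,1,1,1,1,1,3,1,1,1,1,1
4,3,2,4,3,1,4,4,3,3,2,3
2,3,3,1,2,2,4,4,3,2,2,2
3,4,4,4,4,1,4,2,2,2,1,2
3,3,4,2,2,2,2,3,3,2,3,1
3,2,2,2,2,3,4,4,4,3,4,3
4,4,4,3,1,1,4,4,1,2,2,2
4,4,1,4,2,2,4,4,4,3,2,2
4,3,3,1,2,1,1,1,1,1,1,1
3,3,2,1,1,1,2,2,4,1,1,1
4,2,2,1,2,1,2,1,1,1,1,1
1,1,1,1,1,1,4,3,3,3,1,3
4,4,4,4,4,3,4,2,2,1,1,1
2,4,1,1,1,1,3,4,4,3,2,1
4,3,3,3,2,1,2,3,2,2,1,1
4,4,4,4,2,3,1,2,3,1,1,1
4,4,3,4,4,4,3,1,2,2,1,1
3,4,3,4,2,3,3,4,2,1,2,2
4,4,4,3,1,1,3,3,3,1,1,2
3,2,2,1,1,1,4,4,3,4,4,3
2,4,2,2,2,1,4,3,3,4,1,1
4,2,3,2,1,1,4,2,2,3,1,1
4,4,4,NA,4,3,3,2,2,2,2,2
4,4,4,4,4,4,4,4,4,4,4,3
4,4,3,4,1,2,4,4,2,2,2,1
3,3,2,2,1,1,4,3,3,1,1,1
2,1,3,1,1,1,4,1,1,2,1,1
4,4,4,4,3,3,3,3,4,2,1,1
2,3,3,2,1,1,4,3,3,2,2,1
3,4,3,2,1,2,4,4,1,3,2,1
3,4,3,2,1,2,4,3,1,3,1,1
3,2,3,2,1,1,4,3,4,3,3,4
4,4,4,4,4,3,4,3,4,3,2,1
1,1,2,1,1,1,3,2,3,3,2,1
4,4,4,3,4,3,3,3,3,4,1,1
3,2,1,2,1,2,4,4,3,2,2,2
4,4,4,4,3,3,3,4,2,2,2,1
4,4,3,4,3,3,4,3,4,3,3,1
3,2,1,2,1,1,4,4,4,2,3,4
4,4,4,3,2,2,3,3,1,3,2,1
4,4,4,4,4,3,4,4,4,4,3,2
1,1,1,1,1,1,4,3,3,3,3,1
3,3,4,2,3,2,1,4,3,3,2,3
2,2,3,1,1,1,3,3,2,2,1,1
4,4,4,4,3,2,4,3,3,2,2,3
3,4,4,2,2,1,3,2,1,1,1,1
2,2,1,1,1,1,3,4,2,1,2,1
4,4,4,3,4,3,2,2,1,3,1,1
2,2,1,2,1,1,2,2,2,3,1,1
4,3,3,3,1,2,4,3,2,4,4,1
3,3,1,2,3,1,4,2,2,2,3,1
2,1,1,1,1,1,2,2,1,1,1,1
4,2,3,2,2,1,3,3,2,3,1,1
4,4,2,4,2,3,4,3,3,4,3,3
4,3,3,3,1,1,2,1,2,1,1,1
4,4,4,3,1,2,3,3,2,2,1,1
2,4,1,2,1,1,2,1,1,1,1,1
4,4,4,4,4,4,4,4,4,4,1,1
1,2,2,2,1,1,3,3,2,2,1,1
3,2,4,3,3,2,4,4,4,2,3,2
4,4,4,4,4,3,3,4,3,2,4,1
2,1,1,1,1,1,4,4,4,4,2,4
1,2,3,3,1,1,4,4,2,2,3,2
3,2,2,2,1,1,4,3,4,4,3,3
4,4,2,2,1,1,4,4,4,3,4,3
3,4,4,3,2,4,2,2,1,1,1,NA
2,2,1,2,1,1,4,4,4,4,4,4
3,2,1,1,1,1,4,1,4,3,2,2
4,2,3,2,2,1,1,2,3,1,2,1
4,4,4,4,4,4,1,1,1,1,1,2
1,4,1,1,1,1,4,4,4,4,3,3
3,2,2,1,1,1,4,4,3,3,3,3
2,1,2,1,1,2,4,3,1,2,2,2
3,2,2,1,1,1,4,4,3,4,4,2
3,4,3,3,3,2,3,3,2,2,1,2
3,2,2,1,2,1,4,4,3,4,3,2
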