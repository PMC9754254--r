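case_id,slide_id,accession,error_type,dx_class,ai_class
1,C1.B1.S1,C1,FN,D,M
2,C2.B1.S1,C2,FN,N,M
3,C3.B1.S1,C3,FN,N,D
4,C4.B1.S1,C4,FN,N,D
5,C5.B1.S1,C5,FN,N,D
6,C6.B1.S1,C6,FP,D,N
7,C7.B1.S1,C7,switching,D,N
7,C7.B2.S1,C7,switching,N,D
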