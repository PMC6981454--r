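compound_id,cell_line,ic50_um,censored
4a,CFPAC-1,25,TRUE
4a,NCI-H460,25,TRUE
4a,HL-60,25,TRUE
4a,CACO2,100,TRUE
4a,HCT-116,25,TRUE
4a,K562,25,TRUE
4a,MCF-7,25,TRUE
4a,MRC-5,100,TRUE
4b,CFPAC-1,25,TRUE
4b,NCI-H460,25,TRUE
4b,HL-60,25,TRUE
4b,CACO2,100,TRUE
4b,HCT-116,25,TRUE
4b,K562,25,TRUE
4b,MCF-7,25,TRUE
4b,MRC-5,100,TRUE
4c,CFPAC-1,25,TRUE
4c,NCI-H460,21,FALSE
4c,HL-60,15,FALSE
4c,CACO2,100,TRUE
4c,HCT-116,25,TRUE
4c,K562,25,TRUE
4c,MCF-7,25,TRUE
4c,MRC-5,100,TRUE
4d,CFPAC-1,25,TRUE
4d,NCI-H460,25,TRUE
4d,HL-60,16,FALSE
4d,CACO2,100,TRUE
4d,HCT-116,25,TRUE
4d,K562,25,TRUE
4d,MCF-7,25,TRUE
4d,MRC-5,100,TRUE
4e,CFPAC-1,25,TRUE
4e,NCI-H460,25,TRUE
4e,HL-60,18,FALSE
4e,CACO2,100,TRUE
4e,HCT-116,25,TRUE
4e,K562,25,TRUE
4e,MCF-7,25,TRUE
4e,MRC-5,100,TRUE
4f,CFPAC-1,25,TRUE
4f,NCI-H460,25,TRUE
4f,HL-60,17,FALSE
4f,CACO2,100,TRUE
4f,HCT-116,25,TRUE
4f,K562,25,TRUE
4f,MCF-7,25,TRUE
4f,MRC-5,100,TRUE
4g,CFPAC-1,25,TRUE
4g,NCI-H460,18,FALSE
4g,HL-60,12,FALSE
4g,CACO2,100,TRUE
4g,HCT-116,25,TRUE
4g,K562,25,TRUE
4g,MCF-7,25,TRUE
4g,MRC-5,100,TRUE
4h,CFPAC-1,25,TRUE
4h,NCI-H460,25,TRUE
4h,HL-60,13,FALSE
4h,CACO2,100,TRUE
4h,HCT-116,25,TRUE
4h,K562,25,TRUE
4h,MCF-7,25,TRUE
4h,MRC-5,100,TRUE
4i,CFPAC-1,25,TRUE
4i,NCI-H460,25,TRUE
4i,HL-60,12,FALSE
4i,CACO2,100,TRUE
4i,HCT-116,25,TRUE
4i,K562,25,TRUE
4i,MCF-7,25,TRUE
4i,MRC-5,100,TRUE
4j,CFPAC-1,25,TRUE
4j,NCI-H460,25,TRUE
4j,HL-60,5.8,FALSE
4j,CACO2,100,TRUE
4j,HCT-116,25,TRUE
4j,K562,25,TRUE
4j,MCF-7,25,TRUE
4j,MRC-5,50,FALSE
4k,CFPAC-1,25,TRUE
4k,NCI-H460,25,TRUE
4k,HL-60,14,FALSE
4k,CACO2,100,TRUE
4k,HCT-116,25,TRUE
4k,K562,25,TRUE
4k,MCF-7,25,TRUE
4k,MRC-5,100,TRUE
4l,CFPAC-1,25,TRUE
4l,NCI-H460,25,TRUE
4l,HL-60,25,TRUE
4l,CACO2,100,TRUE
4l,HCT-116,25,TRUE
4l,K562,25,TRUE
4l,MCF-7,25,TRUE
4l,MRC-5,100,TRUE
4m,CFPAC-1,25,TRUE
4m,NCI-H460,25,TRUE
4m,HL-60,25,TRUE
4m,CACO2,100,TRUE
4m,HCT-116,25,TRUE
4m,K562,25,TRUE
4m,MCF-7,25,TRUE
4m,MRC-5,100,TRUE
4n,CFPAC-1,25,TRUE
4n,NCI-H460,12,FALSE
4n,HL-60,10,FALSE
4n,CACO2,100,TRUE
4n,HCT-116,25,TRUE
4n,K562,25,TRUE
4n,MCF-7,25,TRUE
4n,MRC-5,100,TRUE
4o,CFPAC-1,25,TRUE
4o,NCI-H460,25,TRUE
4o,HL-60,25,TRUE
4o,CACO2,100,TRUE
4o,HCT-116,25,TRUE
4o,K562,25,TRUE
4o,MCF-7,25,TRUE
4o,MRC-5,100,TRUE
4p,CFPAC-1,25,TRUE
4p,NCI-H460,25,TRUE
4p,HL-60,25,TRUE
4p,CACO2,100,TRUE
4p,HCT-116,25,TRUE
4p,K562,25,TRUE
4p,MCF-7,25,TRUE
4p,MRC-5,100,TRUE
4q,CFPAC-1,25,TRUE
4q,NCI-H460,25,TRUE
4q,HL-60,25,TRUE
4q,CACO2,100,TRUE
4q,HCT-116,25,TRUE
4q,K562,25,TRUE
4q,MCF-7,25,TRUE
4q,MRC-5,100,TRUE
4r,CFPAC-1,25,TRUE
4r,NCI-H460,11,FALSE
4r,HL-60,8,FALSE
4r,CACO2,27,FALSE
4r,HCT-116,25,TRUE
4r,K562,25,TRUE
4r,MCF-7,25,TRUE
4r,MRC-5,100,TRUE
4s,CFPAC-1,25,TRUE
4s,NCI-H460,16,FALSE
4s,HL-60,25,TRUE
4s,CACO2,100,TRUE
4s,HCT-116,25,TRUE
4s,K562,25,TRUE
4s,MCF-7,25,TRUE
4s,MRC-5,100,TRUE
4t,CFPAC-1,25,TRUE
4t,NCI-H460,25,TRUE
4t,HL-60,25,TRUE
4t,CACO2,100,TRUE
4t,HCT-116,25,TRUE
4t,K562,25,TRUE
4t,MCF-7,25,TRUE
4t,MRC-5,100,TRUE
4u,CFPAC-1,25,TRUE
4u,NCI-H460,25,TRUE
4u,HL-60,25,TRUE
4u,CACO2,100,TRUE
4u,HCT-116,25,TRUE
4u,K562,25,TRUE
4u,MCF-7,25,TRUE
4u,MRC-5,100,TRUE
7a,CFPAC-1,25,TRUE
7a,NCI-H460,5.5,FALSE
7a,HL-60,2.5,FALSE
7a,CACO2,100,TRUE
7a,HCT-116,20,FALSE
7a,K562,1,FALSE
7a,MCF-7,1.5,FALSE
7a,MRC-5,100,FALSE
7b,CFPAC-1,25,TRUE
7b,NCI-H460,25,TRUE
7b,HL-60,25,TRUE
7b,CACO2,100,TRUE
7b,HCT-116,25,TRUE
7b,K562,25,TRUE
7b,MCF-7,25,TRUE
7b,MRC-5,100,TRUE
7c,CFPAC-1,25,TRUE
7c,NCI-H460,4.8,FALSE
7c,HL-60,6.5,FALSE
7c,CACO2,100,TRUE
7c,HCT-116,25,TRUE
7c,K562,1.5,FALSE
7c,MCF-7,1.5,FALSE
7c,MRC-5,100,FALSE
7d,CFPAC-1,25,TRUE
7d,NCI-H460,8.2,FALSE
7d,HL-60,4,FALSE
7d,CACO2,100,TRUE
7d,HCT-116,25,TRUE
7d,K562,8,FALSE
7d,MCF-7,15,FALSE
7d,MRC-5,100,FALSE
7e,CFPAC-1,25,TRUE
7e,NCI-H460,9,FALSE
7e,HL-60,5,FALSE
7e,CACO2,100,TRUE
7e,HCT-116,25,TRUE
7e,K562,12,FALSE
7e,MCF-7,18,FALSE
7e,MRC-5,100,FALSE
7f,CFPAC-1,25,TRUE
7f,NCI-H460,6.5,FALSE
7f,HL-60,1.3,FALSE
7f,CACO2,100,TRUE
7f,HCT-116,25,TRUE
7f,K562,6,FALSE
7f,MCF-7,10,FALSE
7f,MRC-5,100,FALSE
7g,CFPAC-1,25,TRUE
7g,NCI-H460,2.2,FALSE
7g,HL-60,0.3,FALSE
7g,CACO2,100,TRUE
7g,HCT-116,25,TRUE
7g,K562,3,FALSE
7g,MCF-7,0.7,FALSE
7g,MRC-5,2.4,FALSE
7h,CFPAC-1,25,TRUE
7h,NCI-H460,1.3,FALSE
7h,HL-60,0.4,FALSE
7h,CACO2,100,TRUE
7h,HCT-116,25,TRUE
7h,K562,0.7,FALSE
7h,MCF-7,0.8,FALSE
7h,MRC-5,100,FALSE
7i,CFPAC-1,25,TRUE
7i,NCI-H460,7.8,FALSE
7i,HL-60,3,FALSE
7i,CACO2,100,TRUE
7i,HCT-116,25,TRUE
7i,K562,9,FALSE
7i,MCF-7,14,FALSE
7i,MRC-5,100,FALSE
7j,CFPAC-1,25,TRUE
7j,NCI-H460,9.5,FALSE
7j,HL-60,1.8,FALSE
7j,CACO2,100,TRUE
7j,HCT-116,25,TRUE
7j,K562,10,FALSE
7j,MCF-7,12,FALSE
7j,MRC-5,100,FALSE
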