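compound_id,name,herbs,mw,alogp,hbd,hba,hia_prob,bbb_prob,q_value
445858,Ferulic acid,DG;CX;FL,194.19,1.53,2,4,0.96,0.60,6.76E-03
5321018,Atractylenolide I,BZ,230.31,3.51,0,2,0.99,0.97,9.72E-03
5319022,Ligustilide,DG;CX,190.24,2.87,0,2,1,0.99,6.76E-03
14296,Tetramethylpyrazine,CX,136.2,1.71,0,2,0.99,1,9.72E-04
11521428,Senkyunolide I,CX,224.26,1.04,2,4,0.94,0.81,6.76E-03
3085257,Senkyunolide A,DG;CX,192.26,2.75,0,2,1,0.99,3.68E-02
370,Gallic acid,CX;BS;FL,170.12,0.54,4,4,0.78,0.53,1.36E-04
61361,3-butylphthalide,DG;CX,190.24,3.09,0,2,1,0.99,6.76E-03
642376,Z-butylidenephthalide,DG;CX,188.23,3,0,2,1,0.99,6.76E-03
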