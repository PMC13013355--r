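gt_stage,pred_stage,count
IIB,IIB,207
IIIA,IIIB,22
IIIB,IIIA,4
IIIB,IVA,50
IIA,IB,6
IB,IVA,16
IVA,IB,1
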