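modality,classifier,tp,fp,tn,fn
velscope,lda,35,7,28,0
velscope,qda,34,6,29,1
raman,lda,30,7,28,5
raman,qda,30,7,28,5
fused,lda,35,2,33,0
fused,qda,35,2,33,0
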