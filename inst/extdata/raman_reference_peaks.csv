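label,position
collagen,855
collagen,938
collagen,1245
collagen,1450
collagen,1660
glycosaminoglycan,480
glycosaminoglycan,940
glycosaminoglycan,1060
glycosaminoglycan,1375
cellular,720
cellular,1003
cellular,1300
cellular,1575
cellular,1680
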