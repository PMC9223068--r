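activity,label,tp,tn,fp,fn
backward_fall,FALL,17,0,0,5
forward_fall,FALL,22,0,0,0
left_fall,FALL,21,0,0,1
right_fall,FALL,21,0,0,1
run,ADL,0,20,2,0
jump,ADL,0,22,0,0
sitting_down,ADL,0,21,1,0
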