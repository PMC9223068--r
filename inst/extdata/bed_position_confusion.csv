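predicted,NO_PRESENCE,SITTING_IN_RIGHT_EDGE,LYING_IN_MIDDLE,LYING_IN_RIGHT_EDGE,LYING_IN_LEFT_EDGE,SITTING_IN_LEFT_EDGE
NO_PRESENCE,11,0,0,0,0,0
SITTING_IN_RIGHT_EDGE,0,11,0,0,0,0
LYING_IN_MIDDLE,0,0,11,1,0,0
LYING_IN_RIGHT_EDGE,0,0,0,10,0,0
LYING_IN_LEFT_EDGE,0,0,0,0,11,5
SITTING_IN_LEFT_EDGE,0,0,0,0,0,6
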