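chain,resnum,generic
A,90,2x64
A,110,3x28
A,111,3x29
A,114,3x32
A,115,3x33
A,118,3x36
A,150,4x56
A,151,4x57
A,154,4x60
A,155,4x61
A,170,45x50
A,171,45x51
A,172,45x52
A,173,45x53
A,190,5x36
A,193,5x39
A,194,5x40
A,197,5x43
A,198,5x44
A,200,5x46
A,240,6x48
A,243,6x51
A,244,6x52
A,247,6x55
A,270,7x38
A,274,7x42
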