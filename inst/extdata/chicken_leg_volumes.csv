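config_id,replicate,volume_mm3
Comp.,C1,254145
Comp.,C2,239256
Comp.,C3,277954
Comp.,C4,286303
1/2 Acc.,C1,304247
1/2 Acc.,C2,305351
1/2 Acc.,C3,272516
1/2 Acc.,C4,277740
1/4 Acc.,C1,262466
1/4 Acc.,C2,286887
1/4 Acc.,C3,279901
1/4 Acc.,C4,274849
1/8 Acc.,C1,295410
1/8 Acc.,C2,310579
1/8 Acc.,C3,291054
1/8 Acc.,C4,304708
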