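device origami
layer 1 paper wax_buffered
layer 2 paper wax_buffered
layer 3 paper wax_buffered

> circle id=hub d=5 layer=1
>> rect id=hub_a1 len=6.666666667 w=1.5 attach=abut
>> rect id=hub_a2 len=6.666666667 w=1.5 angle=90 attach=abut
>> rect id=hub_a3 len=6.666666667 w=1.5 angle=180 attach=abut
>> rect id=hub_a4 len=6.666666667 w=1.5 angle=270 attach=abut
> circle id=corners d=2.5 layer=2
>> circle id=corners_d1 d=3 angle=45 dist=6.666666667
>> circle id=corners_d2 d=3 angle=135 dist=6.666666667
>> circle id=corners_d3 d=3 angle=225 dist=6.666666667
>> circle id=corners_d4 d=3 angle=315 dist=6.666666667
> circle id=pool d=10 angle=45 dist=2.5 layer=3
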