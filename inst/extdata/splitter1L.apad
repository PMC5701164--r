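device splitter1L
param arm = 9
layer 1 paper wax_buffered

> circle id=center d=6 layer=1
>> rect id=ch1 len=arm w=1.2 angle=90 attach=abut
>>> circle id=zone1 d=4 angle=90 attach=abut
>> rect id=ch2 len=arm w=1.2 angle=210 attach=abut
>>> circle id=zone2 d=4 angle=210 attach=abut
>> rect id=ch3 len=arm w=1.2 angle=330 attach=abut
>>> circle id=zone3 d=4 angle=330 attach=abut
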