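device twoDPN
param leg = 12
layer 1 membrane cut

> rect id=source len=8 w=6 rot=0 role=cut layer=1
>> rect id=leg1 len=leg w=2 role=cut angle=270 attach=abut
>>> rect id=leg2 len=leg w=3 role=cut angle=270 attach=abut
>>>> circle id=detect d=5 role=cut angle=270 dist=leg+1.5
> rect id=absorbent len=12 w=6 rot=0 role=cut angle=270 dist=36 layer=1
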