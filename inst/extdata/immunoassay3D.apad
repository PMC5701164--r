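device immunoassay3D
param lat = 10
layer 1 paper wax_buffered
layer 2 adhesive cut
layer 3 paper wax_buffered
layer 4 adhesive cut
layer 5 membrane wax_buffered
layer 6 adhesive cut
layer 7 paper wax_buffered
layer 8 adhesive cut
layer 9 paper wax_buffered
layer 10 adhesive cut

> circle id=sample d=4 layer=1
>> circle id=conjugate d=4 layer=3
>>> circle id=capture d=4 layer=5
>>>> circle id=transfer d=4 layer=7
>>>>> circle id=readout d=4 layer=9
>>>>>> rect id=lateral len=lat w=2 attach=abut
>>>>>>> circle id=terminal d=4 attach=abut
>>>>>>>> circle id=vent d=2 layer=10
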