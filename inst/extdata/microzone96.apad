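device microzone96
layer 1 paper wax_full

> circle id=A1 d=6 layer=1
>> circle id=A2 d=6 dist=9
>>> circle id=A3 d=6 dist=9
>>>> circle id=A4 d=6 dist=9
>>>>> circle id=A5 d=6 dist=9
>>>>>> circle id=A6 d=6 dist=9
>>>>>>> circle id=A7 d=6 dist=9
>>>>>>>> circle id=A8 d=6 dist=9
>>>>>>>>> circle id=A9 d=6 dist=9
>>>>>>>>>> circle id=A10 d=6 dist=9
>>>>>>>>>>> circle id=A11 d=6 dist=9
>>>>>>>>>>>> circle id=A12 d=6 dist=9
>>>>>>>>>>>>> text id=col12 text="12" h=4 angle=90 dist=8.1
>>>>>>>>>>>> text id=col11 text="11" h=4 angle=90 dist=8.1
>>>>>>>>>>> text id=col10 text="10" h=4 angle=90 dist=8.1
>>>>>>>>>> text id=col9 text="9" h=4 angle=90 dist=8.1
>>>>>>>>> text id=col8 text="8" h=4 angle=90 dist=8.1
>>>>>>>> text id=col7 text="7" h=4 angle=90 dist=8.1
>>>>>>> text id=col6 text="6" h=4 angle=90 dist=8.1
>>>>>> text id=col5 text="5" h=4 angle=90 dist=8.1
>>>>> text id=col4 text="4" h=4 angle=90 dist=8.1
>>>> text id=col3 text="3" h=4 angle=90 dist=8.1
>>> text id=col2 text="2" h=4 angle=90 dist=8.1
>> text id=col1 text="1" h=4 angle=90 dist=8.1
>> text id=rowA text="A" h=4 angle=180 dist=8.1
>> circle id=B1 d=6 angle=270 dist=9
>>> circle id=B2 d=6 dist=9
>>>> circle id=B3 d=6 dist=9
>>>>> circle id=B4 d=6 dist=9
>>>>>> circle id=B5 d=6 dist=9
>>>>>>> circle id=B6 d=6 dist=9
>>>>>>>> circle id=B7 d=6 dist=9
>>>>>>>>> circle id=B8 d=6 dist=9
>>>>>>>>>> circle id=B9 d=6 dist=9
>>>>>>>>>>> circle id=B10 d=6 dist=9
>>>>>>>>>>>> circle id=B11 d=6 dist=9
>>>>>>>>>>>>> circle id=B12 d=6 dist=9
>>> text id=rowB text="B" h=4 angle=180 dist=8.1
>>> circle id=C1 d=6 angle=270 dist=9
>>>> circle id=C2 d=6 dist=9
>>>>> circle id=C3 d=6 dist=9
>>>>>> circle id=C4 d=6 dist=9
>>>>>>> circle id=C5 d=6 dist=9
>>>>>>>> circle id=C6 d=6 dist=9
>>>>>>>>> circle id=C7 d=6 dist=9
>>>>>>>>>> circle id=C8 d=6 dist=9
>>>>>>>>>>> circle id=C9 d=6 dist=9
>>>>>>>>>>>> circle id=C10 d=6 dist=9
>>>>>>>>>>>>> circle id=C11 d=6 dist=9
>>>>>>>>>>>>>> circle id=C12 d=6 dist=9
>>>> text id=rowC text="C" h=4 angle=180 dist=8.1
>>>> circle id=D1 d=6 angle=270 dist=9
>>>>> circle id=D2 d=6 dist=9
>>>>>> circle id=D3 d=6 dist=9
>>>>>>> circle id=D4 d=6 dist=9
>>>>>>>> circle id=D5 d=6 dist=9
>>>>>>>>> circle id=D6 d=6 dist=9
>>>>>>>>>> circle id=D7 d=6 dist=9
>>>>>>>>>>> circle id=D8 d=6 dist=9
>>>>>>>>>>>> circle id=D9 d=6 dist=9
>>>>>>>>>>>>> circle id=D10 d=6 dist=9
>>>>>>>>>>>>>> circle id=D11 d=6 dist=9
>>>>>>>>>>>>>>> circle id=D12 d=6 dist=9
>>>>> text id=rowD text="D" h=4 angle=180 dist=8.1
>>>>> circle id=E1 d=6 angle=270 dist=9
>>>>>> circle id=E2 d=6 dist=9
>>>>>>> circle id=E3 d=6 dist=9
>>>>>>>> circle id=E4 d=6 dist=9
>>>>>>>>> circle id=E5 d=6 dist=9
>>>>>>>>>> circle id=E6 d=6 dist=9
>>>>>>>>>>> circle id=E7 d=6 dist=9
>>>>>>>>>>>> circle id=E8 d=6 dist=9
>>>>>>>>>>>>> circle id=E9 d=6 dist=9
>>>>>>>>>>>>>> circle id=E10 d=6 dist=9
>>>>>>>>>>>>>>> circle id=E11 d=6 dist=9
>>>>>>>>>>>>>>>> circle id=E12 d=6 dist=9
>>>>>> text id=rowE text="E" h=4 angle=180 dist=8.1
>>>>>> circle id=F1 d=6 angle=270 dist=9
>>>>>>> circle id=F2 d=6 dist=9
>>>>>>>> circle id=F3 d=6 dist=9
>>>>>>>>> circle id=F4 d=6 dist=9
>>>>>>>>>> circle id=F5 d=6 dist=9
>>>>>>>>>>> circle id=F6 d=6 dist=9
>>>>>>>>>>>> circle id=F7 d=6 dist=9
>>>>>>>>>>>>> circle id=F8 d=6 dist=9
>>>>>>>>>>>>>> circle id=F9 d=6 dist=9
>>>>>>>>>>>>>>> circle id=F10 d=6 dist=9
>>>>>>>>>>>>>>>> circle id=F11 d=6 dist=9
>>>>>>>>>>>>>>>>> circle id=F12 d=6 dist=9
>>>>>>> text id=rowF text="F" h=4 angle=180 dist=8.1
>>>>>>> circle id=G1 d=6 angle=270 dist=9
>>>>>>>> circle id=G2 d=6 dist=9
>>>>>>>>> circle id=G3 d=6 dist=9
>>>>>>>>>> circle id=G4 d=6 dist=9
>>>>>>>>>>> circle id=G5 d=6 dist=9
>>>>>>>>>>>> circle id=G6 d=6 dist=9
>>>>>>>>>>>>> circle id=G7 d=6 dist=9
>>>>>>>>>>>>>> circle id=G8 d=6 dist=9
>>>>>>>>>>>>>>> circle id=G9 d=6 dist=9
>>>>>>>>>>>>>>>> circle id=G10 d=6 dist=9
>>>>>>>>>>>>>>>>> circle id=G11 d=6 dist=9
>>>>>>>>>>>>>>>>>> circle id=G12 d=6 dist=9
>>>>>>>> text id=rowG text="G" h=4 angle=180 dist=8.1
>>>>>>>> circle id=H1 d=6 angle=270 dist=9
>>>>>>>>> circle id=H2 d=6 dist=9
>>>>>>>>>> circle id=H3 d=6 dist=9
>>>>>>>>>>> circle id=H4 d=6 dist=9
>>>>>>>>>>>> circle id=H5 d=6 dist=9
>>>>>>>>>>>>> circle id=H6 d=6 dist=9
>>>>>>>>>>>>>> circle id=H7 d=6 dist=9
>>>>>>>>>>>>>>> circle id=H8 d=6 dist=9
>>>>>>>>>>>>>>>> circle id=H9 d=6 dist=9
>>>>>>>>>>>>>>>>> circle id=H10 d=6 dist=9
>>>>>>>>>>>>>>>>>> circle id=H11 d=6 dist=9
>>>>>>>>>>>>>>>>>>> circle id=H12 d=6 dist=9
>>>>>>>>> text id=rowH text="H" h=4 angle=180 dist=8.1
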