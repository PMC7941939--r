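postcode,imd,lsoa,msoa
SE1 7EH,10231,E01003241,E02000463
SE1 1UL,8423,E01003302,E02000471
AB1 2CD,20518,E01011204,E02001601
KT4 9QX,31056,E01002871,E02000410
LS8 4HT,4112,E01011362,E02001623
ME2 3RS,15894,E01016029,E02002290
NW3 6AB,27761,E01000927,E02000133
OX14 1AA,29984,E01028522,E02004075
PE7 3GH,12650,E01015633,E02002234
RG12 7LN,30125,E01016301,E02002329
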