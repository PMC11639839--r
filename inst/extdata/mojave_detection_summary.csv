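species,season,year_label,placement,detections
coyote,winter,winter 2019-2020,random,30
coyote,winter,winter 2019-2020,strategic,470
coyote,summer,summer 2020,random,22
coyote,summer,summer 2020,strategic,402
coyote,winter,winter 2020-2021,random,27
coyote,winter,winter 2020-2021,strategic,441
coyote,summer,summer 2021,random,22
coyote,summer,summer 2021,strategic,296
jackrabbit,winter,winter 2019-2020,random,3214
jackrabbit,winter,winter 2019-2020,strategic,6621
jackrabbit,summer,summer 2020,random,898
jackrabbit,summer,summer 2020,strategic,5277
jackrabbit,winter,winter 2020-2021,random,742
jackrabbit,winter,winter 2020-2021,strategic,1729
jackrabbit,summer,summer 2021,random,395
jackrabbit,summer,summer 2021,strategic,564
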