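"institution","phase","dimension","subdimension","checked","errors"
"site_a","before","completeness","-",12752909,408036
"site_a","before","validity","range",1087059,902
"site_a","before","validity","format",2010738,0
"site_a","before","accuracy","timeline",2020726,80
"site_a","before","accuracy","business_rule",11839,4
"site_a","before","uniqueness","-",2065265,0
"site_a","before","consistency","relationship",2064602,0
"site_a","after","completeness","-",13236566,0
"site_a","after","validity","range",1311039,0
"site_a","after","validity","format",2065054,0
"site_a","after","accuracy","timeline",2075042,80
"site_a","after","accuracy","business_rule",11981,4
"site_a","after","uniqueness","-",2119581,0
"site_a","after","consistency","relationship",2118918,0
"site_b","before","completeness","-",32044557,4346
"site_b","before","validity","range",4158978,17317
"site_b","before","validity","format",5267658,0
"site_b","before","accuracy","timeline",5269045,939
"site_b","before","accuracy","business_rule",16567,453
"site_b","before","uniqueness","-",5151411,1526
"site_b","before","consistency","relationship",5152799,49144
"site_b","after","completeness","-",30013671,0
"site_b","after","validity","range",3753807,0
"site_b","after","validity","format",4941958,0
"site_b","after","accuracy","timeline",4963940,0
"site_b","after","accuracy","business_rule",13826,395
"site_b","after","uniqueness","-",4831780,0
"site_b","after","consistency","relationship",4830834,0
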