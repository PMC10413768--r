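sex,age_unit,age,L,M,S
male,years,5,-1.6,15,0.085
male,years,6,-1.58,15.458,0.0875
male,years,7,-1.56,15.932,0.09
male,years,8,-1.54,16.422,0.0925
male,years,9,-1.52,16.928,0.095
male,years,10,-1.5,17.45,0.0975
male,years,11,-1.48,17.988,0.1
male,years,12,-1.46,18.542,0.1025
male,years,13,-1.44,19.112,0.105
male,years,14,-1.42,19.698,0.1075
male,years,15,-1.4,20.3,0.11
male,years,16,-1.38,20.918,0.1125
male,years,17,-1.36,21.552,0.115
male,years,18,-1.34,22.202,0.1175
male,years,19,-1.32,22.868,0.12
female,years,5,-1.6,15.2,0.085
female,years,6,-1.58,15.658,0.0875
female,years,7,-1.56,16.132,0.09
female,years,8,-1.54,16.622,0.0925
female,years,9,-1.52,17.128,0.095
female,years,10,-1.5,17.65,0.0975
female,years,11,-1.48,18.188,0.1
female,years,12,-1.46,18.742,0.1025
female,years,13,-1.44,19.312,0.105
female,years,14,-1.42,19.898,0.1075
female,years,15,-1.4,20.5,0.11
female,years,16,-1.38,21.118,0.1125
female,years,17,-1.36,21.752,0.115
female,years,18,-1.34,22.402,0.1175
female,years,19,-1.32,23.068,0.12
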