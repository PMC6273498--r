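case,site,clogp,peak_id,rt_min,area,prior_sites,expected_site,rule_consistent
methyltaxifolin,3',1.21715,M33,50.292,,3',3',TRUE
methyltaxifolin,4',1.21715,M34,51.350,,3',4',TRUE
methyltaxifolin,7,1.29372,M35,52.875,,3',7,TRUE
methyltaxifolin,3,1.40805,M36,53.592,,3',3,TRUE
quercetin-sulphate,5,-0.897894,M71,51.583,,3';7,5,TRUE
quercetin-sulphate,7,0.00210607,M72,52.647,,3';7,7,TRUE
quercetin-sulphate,3',0.0554161,M73,56.300,378222,3';7,4',TRUE
quercetin-sulphate,4',0.0554161,M74,57.033,3335213,3';7,3',TRUE
quercetin-sulphate,3,0.160939,M75,58.173,,3';7,3,TRUE
isorhamnetin-sulphate,5,-0.452683,M81,48.633,,,5,TRUE
isorhamnetin-sulphate,7,0.447317,M82,56.917,,,7,TRUE
isorhamnetin-sulphate,3,0.605693,M83,58.042,,,3,TRUE
isorhamnetin-sulphate,4',0.631748,M84,58.922,,,4',TRUE
isorhamnetin-glucuronide,4',-0.133551,M86,49.212,,,4',TRUE
isorhamnetin-glucuronide,7,0.0320181,M87,50.428,,,7,TRUE
eriodictyol-sulphate,7,0.224621,M106,37.325,,,7,TRUE
eriodictyol-sulphate,3',0.398051,M108,37.708,,,3',TRUE
dihydrokaempferol-sulphate,7,-0.255279,M107,38.200,,,7,TRUE
dihydrokaempferol-sulphate,4',-0.192048,M109,40.383,,,4',TRUE
luteolin-glucuronide,7,0.335925,M113,16.017,,,7,FALSE
luteolin-glucuronide,3',0.188342,M114,16.525,,,3'/4',FALSE
luteolin-glucuronide,4',0.188342,M115,17.425,,,3'/4',FALSE
caffeic-acid-hydrate,3-hydroxy,-0.6414,M142,11.692,,,3-hydroxy,TRUE
caffeic-acid-hydrate,2-hydroxy,-0.5798,M143,12.658,,,2-hydroxy,TRUE
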