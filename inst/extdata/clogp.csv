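structure,aglycone,reaction,site,clogp
3'-O-methyltaxifolin,taxifolin,methylation,3',1.21715
4'-O-methyltaxifolin,taxifolin,methylation,4',1.21715
7-O-methyltaxifolin,taxifolin,methylation,7,1.29372
3-O-methyltaxifolin,taxifolin,methylation,3,1.40805
quercetin-5-O-sulphate,quercetin,sulphation,5,-0.897894
quercetin-7-O-sulphate,quercetin,sulphation,7,0.00210607
quercetin-3'-O-sulphate,quercetin,sulphation,3',0.0554161
quercetin-4'-O-sulphate,quercetin,sulphation,4',0.0554161
quercetin-3-O-sulphate,quercetin,sulphation,3,0.160939
isorhamnetin-5-O-sulphate,isorhamnetin,sulphation,5,-0.452683
isorhamnetin-7-O-sulphate,isorhamnetin,sulphation,7,0.447317
isorhamnetin-3-O-sulphate,isorhamnetin,sulphation,3,0.605693
isorhamnetin-4'-O-sulphate,isorhamnetin,sulphation,4',0.631748
isorhamnetin-4'-O-glucuronide,isorhamnetin,glucuronidation,4',-0.133551
isorhamnetin-7-O-glucuronide,isorhamnetin,glucuronidation,7,0.0320181
eriodictyol-7-O-sulphate,eriodictyol,sulphation,7,0.224621
eriodictyol-3'-O-sulphate,eriodictyol,sulphation,3',0.398051
dihydrokaempferol-7-O-sulphate,dihydrokaempferol,sulphation,7,-0.255279
dihydrokaempferol-4'-O-sulphate,dihydrokaempferol,sulphation,4',-0.192048
luteolin-7-O-glucuronide,luteolin,glucuronidation,7,0.335925
luteolin-3'-O-glucuronide,luteolin,glucuronidation,3',0.188342
luteolin-4'-O-glucuronide,luteolin,glucuronidation,4',0.188342
"3-(3,4-dihydroxyphenyl)-3-hydroxypropanoic acid",caffeic acid hydrate,hydration,3-hydroxy,-0.6414
"3-(3,4-dihydroxyphenyl)-2-hydroxypropanoic acid",caffeic acid hydrate,hydration,2-hydroxy,-0.5798
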