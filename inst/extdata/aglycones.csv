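name,formula,frag_mz,frag_label
taxifolin,C15H12O7,285.0407,[M-H-H2O]-
taxifolin,C15H12O7,241.0524,[M-H-H2O-CO2]-
taxifolin,C15H12O7,177.0253,"1,4B- -2H"
taxifolin,C15H12O7,175.0424,[M-H-H2O-C3O2-C2H2O]-
taxifolin,C15H12O7,125.0290,"1,4A- +2H"
quercetin,C15H10O7,229.0526,
quercetin,C15H10O7,211.0386,
quercetin,C15H10O7,179.0015,
quercetin,C15H10O7,151.0061,
quercetin,C15H10O7,107.0230,
dihydrokaempferol,C15H12O6,269.0431,[M-H-H2O]-
dihydrokaempferol,C15H12O6,259.0613,[M-H-CO]-
dihydrokaempferol,C15H12O6,243.0663,[M-H-CO2]-
dihydrokaempferol,C15H12O6,201.0564,[M-H-CO2-C2H2O]-
dihydrokaempferol,C15H12O6,173.0622,[M-H-CO-CO2-C2H2O]-
dihydrokaempferol,C15H12O6,125.0275,"1,4A- +2H"
eriodictyol,C15H12O6,137.0222,"0,2B-"
eriodictyol,C15H12O6,107.0174,"0,4A-"
eriodictyol,C15H12O6,165.0205,"1,2A-"
methyl taxifolin,C16H14O7,299.05,[M-H-H2O]-
methyl taxifolin,C16H14O7,289.07,[M-H-CO]-
isorhamnetin,C16H12O7,,
luteolin,C15H10O6,217.06,[M-H-C3O2]-
luteolin,C15H10O6,175.03,[M-H-C3O2-C2H2O]-
luteolin,C15H10O6,177.03,"0,4B-"
hydrogenated taxifolin,C15H14O7,287.0565,[M-H-H2O]-
hydrogenated taxifolin,C15H14O7,183.0309,
hydrogenated taxifolin,C15H14O7,165.0249,
hydrogenated taxifolin,C15H14O7,161.0287,
hydrogenated taxifolin,C15H14O7,137.0301,
dihydroxyphenylacetic acid,C8H8O4,123.0458,
dihydrocaffeic acid,C9H10O4,137.0642,[M-H-CO2]-
hydroxyphenylpropanoic acid,C9H10O3,121.07,
hydroxyphenylpropanoic acid,C9H10O3,119.04,
coumaric acid,C9H8O3,119.06,
dihydroferulic acid,C10H12O4,151.0845,
dihydroferulic acid,C10H12O4,149.0632,
dihydroferulic acid,C10H12O4,136.0607,
dihydroferulic acid,C10H12O4,119.0578,
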