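name,formula
hydroxyphenylpropanoic acid,C9H10O3
coumaric acid,C9H8O3
dihydroxyphenylacetic acid,C8H8O4
homovanillic acid,C9H10O4
dihydrocaffeic acid,C9H10O4
caffeic acid,C9H8O4
ferulic acid,C10H10O4
dihydroferulic acid,C10H12O4
hydroxybenzyl alcohol,C7H8O2
hydroxybenzoic acid,C7H6O3
vanillic acid,C8H8O4
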