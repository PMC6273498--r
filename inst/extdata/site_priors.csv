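aglycone,reaction,sites
taxifolin,methylation,3'
quercetin,sulphation,3';7
quercetin,methylation,3'
eriodictyol,sulphation,3';7
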