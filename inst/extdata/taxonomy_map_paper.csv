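# Nominal -> revised taxonomy for the complex: before the revision all
# sixteen species were filed under the single nominal Niphargus stygius
# (sensu lato).
nominal,revised
Niphargus stygius,Niphargus brachytelson
Niphargus stygius,Niphargus chagankae
Niphargus stygius,Niphargus cvajcki
Niphargus stygius,Niphargus goricae
Niphargus stygius,Niphargus gottscheeanensis
Niphargus stygius,Niphargus iskae
Niphargus stygius,Niphargus kapelanus
Niphargus stygius,Niphargus karamani
Niphargus stygius,Niphargus kenki
Niphargus stygius,Niphargus kordunenensis
Niphargus stygius,Niphargus likanus
Niphargus stygius,Niphargus malagorae
Niphargus stygius,Niphargus novomestanus
Niphargus stygius,Niphargus podpecanus
Niphargus stygius,Niphargus stygius
Niphargus stygius,Niphargus zagrebensis
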