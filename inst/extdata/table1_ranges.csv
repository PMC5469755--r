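# Transcription of the published range-size / evolutionary-distinctness /
# conservation-rank summary table for the Niphargus stygius species complex
# (16 species). "Single site" rows: n_sites=1, area 0, diameter 0;
# "Two sites" rows: n_sites=2, area 0. Multi-site rows print no site count
# (n_sites=NA). ED in substitutions per nucleotide site.
species,n_sites,area_km2,max_diameter_km,ED,rank
Niphargus brachytelson,1,0,0,0.052,2b
Niphargus chagankae,NA,1679,50,0.042,3
Niphargus cvajcki,NA,139,20,0.080,2a
Niphargus goricae,NA,142,32,0.078,2a
Niphargus gottscheeanensis,NA,1946,65,0.045,3
Niphargus iskae,1,0,0,0.049,2b
Niphargus kapelanus,1,0,0,0.037,2b
Niphargus karamani,1,0,0,0.074,1
Niphargus kenki,NA,1001,106,0.056,2b
Niphargus kordunenensis,1,0,0,0.084,1
Niphargus likanus,2,0,37,0.055,3
Niphargus malagorae,2,0,9,0.064,3
Niphargus novomestanus,NA,228,29,0.038,3
Niphargus podpecanus,NA,871,46,0.051,3
Niphargus stygius,NA,2922,85,0.087,2a
Niphargus zagrebensis,NA,1193,80,0.090,2a
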