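# SYNTHETIC occurrence fixture for the Niphargus stygius complex.
# Species list, countries and the syntopy structure follow the published
# record (type localities; five syntopic caves, three of them pairing
# N. podpecanus with N. gottscheeanensis); coordinates are approximate
# town-level placements and specimen ids are synthetic. 64 distinct sites
# (the published sampling effort): one record per species at its type
# locality, the syntopy additions, and synthetic extra sites for the
# multi-site species consistent with each species' published site class.
specimen_id,species,site_id,lat,lon,country,basin
NS001,Niphargus brachytelson,Lukova_jama,45.55,14.90,Slovenia,Danube
NS002,Niphargus chagankae,Caganka,45.57,15.19,Slovenia,Danube
NS003,Niphargus cvajcki,Solnovo_brezno,45.77,14.93,Slovenia,Danube
NS004,Niphargus goricae,Fram,46.45,15.63,Slovenia,Danube
NS005,Niphargus gottscheeanensis,Zeljnske_jame,45.66,14.90,Slovenia,Danube
NS006,Niphargus iskae,Macji_rep,45.77,14.51,Slovenia,Danube
NS007,Niphargus kapelanus,Bjelolasica,45.23,14.97,Croatia,Danube
NS008,Niphargus karamani,Miljana_well,46.16,15.60,Slovenia,Danube
NS009,Niphargus kenki,Sotla_well,46.15,15.61,Slovenia,Danube
NS010,Niphargus kordunenensis,Mateska_spilja,45.11,15.59,Croatia,Danube
NS011,Niphargus likanus,Dula_Medvednica,45.27,15.23,Croatia,Danube
NS012,Niphargus malagorae,Mivcje_jama,45.74,14.73,Slovenia,Danube
NS013,Niphargus novomestanus,Precna,45.80,15.17,Slovenia,Danube
NS014,Niphargus podpecanus,Podpeska_jama,45.80,14.70,Slovenia,Danube
NS015,Niphargus stygius,Postojna,45.77,14.21,Slovenia,Adriatic
NS016,Niphargus zagrebensis,Zagreb,45.81,15.98,Croatia,Danube
NS017,Niphargus gottscheeanensis,Podpeska_jama,45.80,14.70,Slovenia,Danube
NS018,Niphargus podpecanus,Zeljnske_jame,45.66,14.90,Slovenia,Danube
NS019,Niphargus podpecanus,Kocevje_spring,45.64,14.86,Slovenia,Danube
NS020,Niphargus gottscheeanensis,Kocevje_spring,45.64,14.86,Slovenia,Danube
NS021,Niphargus likanus,Bjelolasica,45.23,14.97,Croatia,Danube
NS022,Niphargus malagorae,Lukova_jama,45.55,14.90,Slovenia,Danube
NS023,Niphargus stygius,stygius_x1,45.7143,14.1065,Slovenia,Adriatic
NS024,Niphargus stygius,stygius_x2,45.8729,14.0829,Slovenia,Adriatic
NS025,Niphargus stygius,stygius_x3,45.7677,13.9736,Slovenia,Adriatic
NS026,Niphargus stygius,stygius_x4,45.8216,14.2194,Slovenia,Adriatic
NS027,Niphargus stygius,stygius_x5,45.8796,14.2179,Slovenia,Adriatic
NS028,Niphargus stygius,stygius_x6,45.6103,14.289,Slovenia,Adriatic
NS029,Niphargus stygius,stygius_x7,45.8367,13.9908,Slovenia,Adriatic
NS030,Niphargus stygius,stygius_x8,45.7088,14.0726,Slovenia,Adriatic
NS031,Niphargus zagrebensis,zagrebensis_x1,45.9169,16.1645,Croatia,Danube
NS032,Niphargus zagrebensis,zagrebensis_x2,45.7524,16.0939,Croatia,Danube
NS033,Niphargus zagrebensis,zagrebensis_x3,45.6985,16.0437,Croatia,Danube
NS034,Niphargus zagrebensis,zagrebensis_x4,45.9496,15.9921,Croatia,Danube
NS035,Niphargus zagrebensis,zagrebensis_x5,45.8334,15.9385,Croatia,Danube
NS036,Niphargus gottscheeanensis,gottscheeanensis_x1,45.5339,14.7796,Slovenia,Danube
NS037,Niphargus gottscheeanensis,gottscheeanensis_x2,45.5194,15.1266,Slovenia,Danube
NS038,Niphargus gottscheeanensis,gottscheeanensis_x3,45.6628,15.0422,Slovenia,Danube
NS039,Niphargus gottscheeanensis,gottscheeanensis_x4,45.7578,15.1178,Slovenia,Danube
NS040,Niphargus gottscheeanensis,gottscheeanensis_x5,45.5007,14.7864,Slovenia,Danube
NS041,Niphargus chagankae,chagankae_x1,45.6605,15.0269,Slovenia,Danube
NS042,Niphargus chagankae,chagankae_x2,45.5522,15.1953,Slovenia,Danube
NS043,Niphargus chagankae,chagankae_x3,45.5513,14.9776,Slovenia,Danube
NS044,Niphargus chagankae,chagankae_x4,45.4577,15.2455,Slovenia,Danube
NS045,Niphargus chagankae,chagankae_x5,45.4805,15.0605,Slovenia,Danube
NS046,Niphargus kenki,kenki_x1,46.2017,15.4388,Slovenia,Danube
NS047,Niphargus kenki,kenki_x2,46.0596,15.3935,Slovenia,Danube
NS048,Niphargus kenki,kenki_x3,46.1649,15.6271,Slovenia,Danube
NS049,Niphargus kenki,kenki_x4,46.0602,15.7775,Slovenia,Danube
NS050,Niphargus kenki,kenki_x5,46.1729,15.6193,Slovenia,Danube
NS051,Niphargus kenki,kenki_x6,46.1747,15.4672,Slovenia,Danube
NS052,Niphargus podpecanus,podpecanus_x1,45.6253,14.7747,Slovenia,Danube
NS053,Niphargus podpecanus,podpecanus_x2,45.9164,14.4799,Slovenia,Danube
NS054,Niphargus podpecanus,podpecanus_x3,45.8624,14.8783,Slovenia,Danube
NS055,Niphargus podpecanus,podpecanus_x4,45.7726,14.9139,Slovenia,Danube
NS056,Niphargus podpecanus,podpecanus_x5,45.7752,14.7294,Slovenia,Danube
NS057,Niphargus novomestanus,novomestanus_x1,45.9059,15.1789,Slovenia,Danube
NS058,Niphargus novomestanus,novomestanus_x2,45.8775,14.9572,Slovenia,Danube
NS059,Niphargus novomestanus,novomestanus_x3,45.625,15.3929,Slovenia,Danube
NS060,Niphargus novomestanus,novomestanus_x4,45.7232,15.1516,Slovenia,Danube
NS061,Niphargus cvajcki,cvajcki_x1,45.7196,14.7111,Slovenia,Danube
NS062,Niphargus cvajcki,cvajcki_x2,45.914,14.9102,Slovenia,Danube
NS063,Niphargus cvajcki,cvajcki_x3,45.8623,15.1571,Slovenia,Danube
NS064,Niphargus cvajcki,cvajcki_x4,45.7608,14.8521,Slovenia,Danube
NS065,Niphargus goricae,goricae_x1,46.2848,15.5549,Slovenia,Danube
NS066,Niphargus goricae,goricae_x2,46.312,15.7024,Slovenia,Danube
NS067,Niphargus goricae,goricae_x3,46.5176,15.552,Slovenia,Danube
NS068,Niphargus goricae,goricae_x4,46.3066,15.8263,Slovenia,Danube
NS069,Niphargus goricae,goricae_x5,46.5331,15.7658,Slovenia,Danube
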