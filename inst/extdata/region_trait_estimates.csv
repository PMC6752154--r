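region,height32_cm,height32_se,height32_letters,dbh27_mm,dbh27_se,dbh27_letters,survival,survival_se,survival_letters,resistance_1999,resistance_1999_se,resistance_1999_letters,recovery_1999,recovery_1999_se,recovery_1999_letters,resistance_2002,resistance_2002_se,resistance_2002_letters,recovery_2002,recovery_2002_se,recovery_2002_letters,resilience,resilience_se,resilience_letters
Boreal Cordillera,546,55,a,63,8,a,0.97,0.02,ab,0.69,0.04,a,1.70,0.14,a,0.64,0.06,a,1.73,0.17,ab,1.10,0.07,a
Montane Cordillera,700,56,b,84,8,b,0.84,0.07,ab,0.60,0.04,ac,1.77,0.15,ad,0.53,0.06,a,2.14,0.12,b,0.95,0.07,a
Maritime Mixedwood,767,64,b,79,9,ab,0.78,0.10,b,0.60,0.05,ac,1.85,0.16,abd,0.69,0.07,a,1.62,0.13,a,1.07,0.07,a
Boreal Plains,908,37,c,116,5,c,0.97,0.01,a,0.50,0.03,bc,2.17,0.11,bcd,0.63,0.05,a,1.72,0.09,a,1.04,0.05,a
Boreal Shield,957,37,c,117,5,c,0.95,0.02,ab,0.44,0.03,b,2.26,0.11,bc,0.55,0.05,a,1.78,0.09,a,0.96,0.05,a
Temperate Mixedwood,966,55,c,122,8,c,0.89,0.05,ab,0.44,0.04,bc,2.43,0.14,c,0.67,0.06,a,1.71,0.12,a,1.04,0.07,a
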