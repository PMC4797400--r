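organ,kinetics,self_gy_per_mbq,total_gy_per_mbq
tumor,in111,2.2,2.3
submandibular,in111,1.9,2.0
blood,in111,1.3,1.3
marrow,in111,0.40,0.47
liver,in111,0.63,0.66
heart,in111,0.47,0.66
lung,in111,0.41,0.54
spleen,in111,0.67,0.71
kidney,in111,0.50,0.53
gi,in111,0.30,0.35
bone,in111,0.13,0.27
brain,in111,0.017,0.040
testes,in111,0.24,0.28
tumor,lu177,4.8,4.9
submandibular,lu177,5.6,5.6
blood,lu177,1.2,1.3
marrow,lu177,0.38,0.45
liver,lu177,1.56,1.59
heart,lu177,0.56,0.74
lung,lu177,0.59,0.71
spleen,lu177,1.9,1.9
kidney,lu177,0.50,0.54
gi,lu177,0.35,0.44
bone,lu177,0.18,0.30
brain,lu177,0.019,0.041
testes,lu177,0.31,0.35
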