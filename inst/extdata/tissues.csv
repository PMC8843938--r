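name,h_fraction,o_fraction,red_nominal
adipose,0.114,0.278,0.951
muscle_skeletal,0.102,0.710,1.050
liver,0.102,0.716,1.060
blood_whole,0.102,0.745,1.060
skin,0.100,0.645,1.090
brain,0.107,0.712,1.040
kidney,0.103,0.724,1.050
lung_deflated,0.103,0.749,1.050
pancreas,0.106,0.694,1.040
spleen,0.103,0.741,1.060
heart,0.104,0.718,1.050
breast,0.106,0.527,1.020
soft_tissue_icru,0.105,0.702,1.030
thyroid,0.104,0.745,1.050
stomach,0.106,0.751,1.050
small_intestine,0.106,0.751,1.030
testis,0.106,0.766,1.040
ovary,0.105,0.768,1.050
cartilage,0.096,0.744,1.100
water,0.1119,0.8881,1.000
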