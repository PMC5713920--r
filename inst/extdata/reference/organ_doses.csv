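organ,group,lateral_small,lateral_large,medial_small,medial_large
breast,main,37.05,50.18,32.53,32.92
stomach,main,16.63,41.89,14.77,36.25
esophagus,main,17.98,33.00,13.94,20.49
thyroid,main,9.97,21.58,11.28,16.93
liver,main,9.22,16.20,7.55,10.18
red_bone_marrow,main,7.28,13.20,5.93,9.61
lung,main,4.90,7.06,4.82,5.04
bone_surface,main,4.22,7.48,3.76,6.08
salivary_glands,main,4.35,7.65,3.87,5.98
colon,main,2.39,4.39,2.43,4.01
skin,main,1.96,6.73,2.05,7.95
brain,main,2.06,3.38,1.64,2.63
ovaries,main,1.58,3.14,1.51,2.53
urinary_bladder,main,1.04,1.73,1.28,2.33
heart,remainder,83.49,86.18,77.93,44.84
thymus,remainder,84.24,102.88,41.67,38.71
pancreas,remainder,12.24,25.39,10.04,19.83
spleen,remainder,11.27,24.23,10.48,25.26
lymphatic_nodes,remainder,10.96,14.83,10.42,10.60
adrenals,remainder,8.83,17.46,6.69,11.63
gall_bladder,remainder,5.82,11.04,5.90,8.52
extra_thoracic_tissue,remainder,5.70,10.82,5.12,8.00
kidneys,remainder,4.87,9.27,3.65,6.55
oral_mucosa,remainder,3.63,7.12,3.59,5.61
small_intestine,remainder,2.66,4.90,2.67,4.41
uterus,remainder,1.56,2.71,1.59,2.66
muscle,remainder,1.24,2.44,1.27,3.34
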