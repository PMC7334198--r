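tissue	n_samples
Adipose_Subcutaneous	442
Adipose_Visceral_Omentum	355
Adrenal_Gland	190
Artery_Aorta	299
Artery_Coronary	173
Artery_Tibial	441
Bladder	9
Brain_Amygdala	100
Brain_Anterior_cingulate_cortex_BA24	121
Brain_Caudate_basal_ganglia	160
Brain_Cerebellar_Hemisphere	136
Brain_Cerebellum	173
Brain_Cortex	158
Brain_Frontal_Cortex_BA9	129
Brain_Hippocampus	123
Brain_Hypothalamus	121
Brain_Nucleus_accumbens_basal_ganglia	147
Brain_Putamen_basal_ganglia	124
Brain_Spinal_cord_cervical_c-1	62
Brain_Substantia_nigra	63
Breast_Mammary_Tissue	290
Cells_EBV-transformed_lymphocytes	130
Cells_Transformed_fibroblasts	343
Cervix_Ectocervix	6
Cervix_Endocervix	5
Colon_Sigmoid	203
Colon_Transverse	245
Esophagus_Gastroesophageal_Junction	213
Esophagus_Mucosa	358
Esophagus_Muscularis	335
Fallopian_Tube	7
Heart_Atrial_Appendage	264
Heart_Left_Ventricle	272
Kidney_Cortex	36
Liver	153
Lung	383
Minor_Salivary_Gland	57
Muscle_Skeletal	491
Nerve_Tibial	361
Ovary	122
Pancreas	220
Pituitary	157
Prostate	132
Skin_Not_Sun_Exposed_Suprapubic	335
Skin_Sun_Exposed_Lower_leg	473
Small_Intestine_Terminal_Ileum	122
Spleen	146
Stomach	237
Testis	225
Thyroid	399
Uterus	101
Vagina	106
Whole_Blood	407
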