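category,etiology_class,etiology,count
M,physiologic,gastrointestinal_peristalsis,15
M,physiologic,urinary_excretion,13
M,physiologic,brown_adipose_tissue,10
M,physiologic,bone_activation,8
M,physiologic,oesophageal_peristalsis,5
M,physiologic,muscle_activation,4
M,physiologic,anal_sphincter,2
M,physiologic,renal_medulla,1
M,benign,musculoskeletal_degenerative_disease,39
M,benign,distant_unspecific_lymph_node,10
M,benign,unspecific_prostate_uptake,8
M,benign,fdg_paravasation_or_contamination,7
M,benign,benign_breast_lesion,3
M,benign,drainage_associated_uptake,2
M,benign,unspecific_uterine_uptake,1
M,pathologic,rib_fracture,15
M,pathologic,pulmonary_inflammation,14
M,pathologic,vertebral_body_fracture,7
M,pathologic,thyroid_gland_uptake,7
M,pathologic,kyphoplasty_associated_uptake,5
M,pathologic,liver_lesion,5
M,pathologic,parotid_inflammation_or_mass,5
M,pathologic,adrenal_adenoma,4
M,pathologic,skin_lesion,3
M,pathologic,colon_polyp,3
T,pathologic,inflammatory_changes,18
T,pathologic,dystelectasis,4
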