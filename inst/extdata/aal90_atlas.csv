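"roi","hemisphere","homologue","lobe"
"Precentral_L","left","Precentral_R","frontal"
"Precentral_R","right","Precentral_L","frontal"
"Frontal_Sup_L","left","Frontal_Sup_R","frontal"
"Frontal_Sup_R","right","Frontal_Sup_L","frontal"
"Frontal_Sup_Orb_L","left","Frontal_Sup_Orb_R","frontal"
"Frontal_Sup_Orb_R","right","Frontal_Sup_Orb_L","frontal"
"Frontal_Mid_L","left","Frontal_Mid_R","frontal"
"Frontal_Mid_R","right","Frontal_Mid_L","frontal"
"Frontal_Mid_Orb_L","left","Frontal_Mid_Orb_R","frontal"
"Frontal_Mid_Orb_R","right","Frontal_Mid_Orb_L","frontal"
"Frontal_Inf_Oper_L","left","Frontal_Inf_Oper_R","frontal"
"Frontal_Inf_Oper_R","right","Frontal_Inf_Oper_L","frontal"
"Frontal_Inf_Tri_L","left","Frontal_Inf_Tri_R","frontal"
"Frontal_Inf_Tri_R","right","Frontal_Inf_Tri_L","frontal"
"Frontal_Inf_Orb_L","left","Frontal_Inf_Orb_R","frontal"
"Frontal_Inf_Orb_R","right","Frontal_Inf_Orb_L","frontal"
"Rolandic_Oper_L","left","Rolandic_Oper_R","frontal"
"Rolandic_Oper_R","right","Rolandic_Oper_L","frontal"
"Supp_Motor_Area_L","left","Supp_Motor_Area_R","frontal"
"Supp_Motor_Area_R","right","Supp_Motor_Area_L","frontal"
"Olfactory_L","left","Olfactory_R","subcortical"
"Olfactory_R","right","Olfactory_L","subcortical"
"Frontal_Sup_Medial_L","left","Frontal_Sup_Medial_R","frontal"
"Frontal_Sup_Medial_R","right","Frontal_Sup_Medial_L","frontal"
"Frontal_Med_Orb_L","left","Frontal_Med_Orb_R","frontal"
"Frontal_Med_Orb_R","right","Frontal_Med_Orb_L","frontal"
"Rectus_L","left","Rectus_R","frontal"
"Rectus_R","right","Rectus_L","frontal"
"Insula_L","left","Insula_R","subcortical"
"Insula_R","right","Insula_L","subcortical"
"Cingulum_Ant_L","left","Cingulum_Ant_R","cingulate"
"Cingulum_Ant_R","right","Cingulum_Ant_L","cingulate"
"Cingulum_Mid_L","left","Cingulum_Mid_R","cingulate"
"Cingulum_Mid_R","right","Cingulum_Mid_L","cingulate"
"Cingulum_Post_L","left","Cingulum_Post_R","cingulate"
"Cingulum_Post_R","right","Cingulum_Post_L","cingulate"
"Hippocampus_L","left","Hippocampus_R","temporal"
"Hippocampus_R","right","Hippocampus_L","temporal"
"ParaHippocampal_L","left","ParaHippocampal_R","temporal"
"ParaHippocampal_R","right","ParaHippocampal_L","temporal"
"Amygdala_L","left","Amygdala_R","subcortical"
"Amygdala_R","right","Amygdala_L","subcortical"
"Calcarine_L","left","Calcarine_R","occipital"
"Calcarine_R","right","Calcarine_L","occipital"
"Cuneus_L","left","Cuneus_R","occipital"
"Cuneus_R","right","Cuneus_L","occipital"
"Lingual_L","left","Lingual_R","occipital"
"Lingual_R","right","Lingual_L","occipital"
"Occipital_Sup_L","left","Occipital_Sup_R","occipital"
"Occipital_Sup_R","right","Occipital_Sup_L","occipital"
"Occipital_Mid_L","left","Occipital_Mid_R","occipital"
"Occipital_Mid_R","right","Occipital_Mid_L","occipital"
"Occipital_Inf_L","left","Occipital_Inf_R","occipital"
"Occipital_Inf_R","right","Occipital_Inf_L","occipital"
"Fusiform_L","left","Fusiform_R","temporal"
"Fusiform_R","right","Fusiform_L","temporal"
"Postcentral_L","left","Postcentral_R","parietal"
"Postcentral_R","right","Postcentral_L","parietal"
"Parietal_Sup_L","left","Parietal_Sup_R","parietal"
"Parietal_Sup_R","right","Parietal_Sup_L","parietal"
"Parietal_Inf_L","left","Parietal_Inf_R","parietal"
"Parietal_Inf_R","right","Parietal_Inf_L","parietal"
"SupraMarginal_L","left","SupraMarginal_R","parietal"
"SupraMarginal_R","right","SupraMarginal_L","parietal"
"Angular_L","left","Angular_R","parietal"
"Angular_R","right","Angular_L","parietal"
"Precuneus_L","left","Precuneus_R","parietal"
"Precuneus_R","right","Precuneus_L","parietal"
"Paracentral_Lobule_L","left","Paracentral_Lobule_R","parietal"
"Paracentral_Lobule_R","right","Paracentral_Lobule_L","parietal"
"Caudate_L","left","Caudate_R","subcortical"
"Caudate_R","right","Caudate_L","subcortical"
"Putamen_L","left","Putamen_R","subcortical"
"Putamen_R","right","Putamen_L","subcortical"
"Pallidum_L","left","Pallidum_R","subcortical"
"Pallidum_R","right","Pallidum_L","subcortical"
"Thalamus_L","left","Thalamus_R","subcortical"
"Thalamus_R","right","Thalamus_L","subcortical"
"Heschl_L","left","Heschl_R","temporal"
"Heschl_R","right","Heschl_L","temporal"
"Temporal_Sup_L","left","Temporal_Sup_R","temporal"
"Temporal_Sup_R","right","Temporal_Sup_L","temporal"
"Temporal_Pole_Sup_L","left","Temporal_Pole_Sup_R","temporal"
"Temporal_Pole_Sup_R","right","Temporal_Pole_Sup_L","temporal"
"Temporal_Mid_L","left","Temporal_Mid_R","temporal"
"Temporal_Mid_R","right","Temporal_Mid_L","temporal"
"Temporal_Pole_Mid_L","left","Temporal_Pole_Mid_R","temporal"
"Temporal_Pole_Mid_R","right","Temporal_Pole_Mid_L","temporal"
"Temporal_Inf_L","left","Temporal_Inf_R","temporal"
"Temporal_Inf_R","right","Temporal_Inf_L","temporal"
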