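label	module_name
LIFG_tri	perisylvian
RIFG_tri	perisylvian
LIFG_oper	perisylvian
RIFG_oper	perisylvian
LIFG_orb	perisylvian
RIFG_orb	perisylvian
L_STG	perisylvian
R_STG	perisylvian
L_supramarginal	perisylvian
R_supramarginal	perisylvian
L_Heschl	perisylvian
R_Heschl	perisylvian
L_insula	perisylvian
R_insula	perisylvian
L_MTG	temporal
R_MTG	temporal
L_ITG	temporal
R_ITG	temporal
L_temporal_pole	temporal
R_temporal_pole	temporal
L_PHG	temporal
R_PHG	temporal
L_entorhinal	temporal
R_entorhinal	temporal
L_hippocampus	temporal
R_hippocampus	temporal
L_amygdala	temporal
R_amygdala	temporal
L_MFG	FP
R_MFG	FP
L_angular	FP
R_angular	FP
L_SPL	FP
R_SPL	FP
L_frontal_pole	FP
R_frontal_pole	FP
L_SFG	dFP
R_SFG	dFP
L_precentral	dFP
R_precentral	dFP
L_postcentral	dFP
R_postcentral	dFP
L_SMA	dFP
R_SMA	dFP
L_MCC	dFP
R_MCC	dFP
L_mOFC	vmPFC
R_mOFC	vmPFC
L_gyrus_rectus	vmPFC
R_gyrus_rectus	vmPFC
L_ACC	vmPFC
R_ACC	vmPFC
L_PCC	vmPFC
R_PCC	vmPFC
L_precuneus	vmPFC
R_precuneus	vmPFC
L_cuneus	occipital-temporal
R_cuneus	occipital-temporal
L_lingual	occipital-temporal
R_lingual	occipital-temporal
L_LOC	occipital-temporal
R_LOC	occipital-temporal
L_pericalcarine	occipital-temporal
R_pericalcarine	occipital-temporal
L_fusiform	occipital-temporal
R_fusiform	occipital-temporal
L_caudate	subcortical
R_caudate	subcortical
L_putamen	subcortical
R_putamen	subcortical
L_pallidum	subcortical
R_pallidum	subcortical
L_thalamus	subcortical
R_thalamus	subcortical
L_accumbens	subcortical
R_accumbens	subcortical
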