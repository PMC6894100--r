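element,surface_form,canonical
histology,small cell,SmallCell
histology,small cell carcinoma,SmallCell
histology,small cell lung cancer,SmallCell
histology,small cell lung carcinoma,SmallCell
histology,small cell cancer,SmallCell
histology,sclc,SmallCell
histology,oat cell carcinoma,SmallCell
histology,smallcell,SmallCell
histology,adenocarcinoma,Adenocarcinoma
histology,adeno carcinoma,Adenocarcinoma
histology,bronchioloalveolar,Adenocarcinoma
histology,bronchioloalveolar carcinoma,Adenocarcinoma
histology,bronchioloalveolar adenocarcinoma,Adenocarcinoma
histology,squamous,Squamous
histology,squamous cell,Squamous
histology,squamous cell carcinoma,Squamous
histology,squamous carcinoma,Squamous
histology,large cell neuroendocrine,LargeNeuroendocrine
histology,large cell neuroendocrine carcinoma,LargeNeuroendocrine
histology,larger neuroendocrine,LargeNeuroendocrine
histology,larger neuroendocrine carcinoma,LargeNeuroendocrine
histology,large neuroendocrine,LargeNeuroendocrine
histology,large neuroendocrine carcinoma,LargeNeuroendocrine
histology,larger cell neuroendocrine,LargeNeuroendocrine
histology,larger cell neuroendocrine carcinoma,LargeNeuroendocrine
histology,largeneuroendocrine,LargeNeuroendocrine
histology,adenosquamous,Adenosquamous
histology,adenosquamous carcinoma,Adenosquamous
histology,typical carcinoid,CarcinoidTypicalAtypical
histology,atypical carcinoid,CarcinoidTypicalAtypical
histology,typical carcinoid tumor,CarcinoidTypicalAtypical
histology,atypical carcinoid tumor,CarcinoidTypicalAtypical
histology,carcinoidtypicalatypical,CarcinoidTypicalAtypical
histology,carcinoid,Carcinoid
histology,carcinoid tumor,Carcinoid
histology,non small cell,NSCLCUnspecified
histology,non small cell carcinoma,NSCLCUnspecified
histology,non small cell lung cancer,NSCLCUnspecified
histology,non small cell lung carcinoma,NSCLCUnspecified
histology,non small cell cancer,NSCLCUnspecified
histology,nsclc,NSCLCUnspecified
histology,nsclcunspecified,NSCLCUnspecified
histology,sarcomatoid carcinoma,OtherNSCLC
histology,pleomorphic carcinoma,OtherNSCLC
histology,giant cell carcinoma,OtherNSCLC
histology,othernsclc,OtherNSCLC
histology,unknown cell type,OtherUnknown
histology,cell type unknown,OtherUnknown
histology,other cell type,OtherUnknown
histology,otherunknown,OtherUnknown
stage,ia,Ia
stage,1a,Ia
stage,ib,Ib
stage,1b,Ib
stage,iia,IIa
stage,2a,IIa
stage,iib,IIb
stage,2b,IIb
stage,iiia,IIIa
stage,3a,IIIa
stage,iiib,IIIb
stage,3b,IIIb
stage,iv,IV
stage,4,IV
stage,early stage,EarlyStage
stage,earlystage,EarlyStage
stage,late stage,LateStage
stage,latestage,LateStage
stage,limited,Limited
stage,limited stage,Limited
stage,limited disease,Limited
stage,limited stage disease,Limited
stage,extensive,Extensive
stage,extensive stage,Extensive
stage,extensive stage disease,Extensive
stage,extensive disease,Extensive
grade,1,WellDifferentiated
grade,i,WellDifferentiated
grade,grade 1,WellDifferentiated
grade,grade i,WellDifferentiated
grade,well differentiated,WellDifferentiated
grade,welldifferentiated,WellDifferentiated
grade,2,ModeratelyDifferentiated
grade,ii,ModeratelyDifferentiated
grade,grade 2,ModeratelyDifferentiated
grade,grade ii,ModeratelyDifferentiated
grade,moderately differentiated,ModeratelyDifferentiated
grade,moderatelydifferentiated,ModeratelyDifferentiated
grade,3,PoorlyDifferentiated
grade,iii,PoorlyDifferentiated
grade,grade 3,PoorlyDifferentiated
grade,grade iii,PoorlyDifferentiated
grade,poorly differentiated,PoorlyDifferentiated
grade,poorlydifferentiated,PoorlyDifferentiated
grade,4,Undifferentiated
grade,iv,Undifferentiated
grade,grade 4,Undifferentiated
grade,grade iv,Undifferentiated
grade,undifferentiated,Undifferentiated
chemotherapy,chemotherapy,chemotherapy
chemotherapy,chemo,chemotherapy
chemotherapy,carboplatin,chemotherapy
chemotherapy,cisplatin,chemotherapy
chemotherapy,paclitaxel,chemotherapy
chemotherapy,etoposide,chemotherapy
chemotherapy,pemetrexed,chemotherapy
chemotherapy,gemcitabine,chemotherapy
radiotherapy,radiation therapy,radiotherapy
radiotherapy,radiotherapy,radiotherapy
radiotherapy,radiation treatment,radiotherapy
radiotherapy,xrt,radiotherapy
radiotherapy,combined modality,radiotherapy
surgery,surgery,surgery
surgery,lobectomy,surgery
surgery,pneumonectomy,surgery
surgery,segmentectomy,surgery
surgery,wedge resection,surgery
surgery,thoracotomy,surgery
surgery,status post lung cancer surgery,surgery
surgery,lung cancer surgery,surgery
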