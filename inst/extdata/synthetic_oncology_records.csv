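drug_name,modality_class,molecular_weight_kda,nonclin_dose_value,nonclin_dose_unit,nonclin_n_admin_day1,nonclin_species,nonclin_route,nonclin_model,nonclin_response_metric,nonclin_response_value,clin_dose_low,clin_dose_high,clin_dose_unit,clin_route,indication,flags,reference
syn-kinib-01,SM_PO,0.43,25,mg_per_kg,1,mouse,PO,NSCLC xenograft,TGI_percent,72,150,NA,mg,PO,NSCLC (synthetic),,synthetic record
syn-taxoid-02,SM_IV,0.85,10,mg_per_kg,1,mouse,IV,breast xenograft,stasis,NA,30,NA,mg_per_m2,IV,breast (synthetic),,synthetic record
syn-tinib-03,SM_PO,0.49,50,mg_per_kg,1,mouse,PO,colon xenograft,TGI_percent,66,40,60,mg,PO,CRC (synthetic),,synthetic record
syn-imid-04,SM_IO_HT,0.26,30,mg_per_kg,1,mouse,PO,myeloma xenograft,TGI_percent,61,25,NA,mg,PO,MM (synthetic),,synthetic record
syn-mab-05,mAb,149,5,mg_per_kg,1,mouse,IV,gastric xenograft,regression,NA,4,NA,mg_per_kg,IV,gastric (synthetic),,synthetic record
syn-pdmab-06,checkpoint,146,10,mg_per_kg,1,mouse,IP,melanoma xenograft,TGI_percent,68,3,NA,mg_per_kg,IV,melanoma (synthetic),,synthetic record
syn-adc-07,ADC,153,3,mg_per_kg,1,mouse,IV,lymphoma xenograft,regression,NA,1.8,NA,mg_per_kg,IV,DLBCL (synthetic),,synthetic record
syn-bite-08,bispecific,54.1,0.5,mg_per_kg,2,mouse,IV,leukemia xenograft,survival,NA,0.08,NA,mg_per_kg,IV,ALL (synthetic),,synthetic record
syn-cytotox-09,SM_IV,0.31,80,mg_per_kg,1,mouse,IV,sarcoma xenograft,TGI_percent,90,90,NA,mg_per_m2,IV,sarcoma (synthetic),mtd_only,synthetic record
syn-syng-10,mAb,150,8,mg_per_kg,1,mouse,IV,syngeneic CT26,TGI_percent,75,6,NA,mg_per_kg,IV,CRC (synthetic),syngeneic_model,synthetic record
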