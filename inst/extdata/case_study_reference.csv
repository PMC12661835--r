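dataset,model,n_prime_max,baseline_auc,augmented_auc,relative_auc_pct,resampled_auc,diversity_generative,diversity_resample
Breast Cancer,CTGAN,25,0.7143,0.7451,4.31,0.6729,0.0017,0.0008
Breast Cancer Coimbra,BN,53,0.7392,0.8722,18.00,0.8291,0.0061,0.0019
Colposcopy/Schiller,CTGAN,2205,0.5125,0.7341,43.23,0.6116,0.0883,0.0004
Danish Colorectal Cancer Group,TVAE,720,0.7171,0.7780,8.50,0.7077,0.0000,0.0008
Diabetic Retinopathy,BN,11534,0.7400,0.7974,7.75,0.7299,0.1177,0.0002
Hot Flashes,CTGAN,720,0.7161,0.7668,7.08,0.6477,0.0023,0.0013
Thoracic Surgery,TVAE,6602,0.5584,0.6700,19.98,0.6914,0.0000,0.0003
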