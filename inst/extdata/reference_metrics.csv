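model,feature_category,selection_method,n_features,optimizer,c,g,accuracy,precision,recall,f1
svm,spectral,full_spectrum,200,none,NA,NA,88.75,90.83,87.20,88.98
svm,spectral,spa,33,none,NA,NA,89.58,92.50,87.40,89.88
svm,image,glcm,28,none,NA,NA,56.25,75.00,54.55,63.16
svm,fusion,full_spectrum_glcm,228,none,NA,NA,90.83,92.50,89.52,90.99
svm,fusion,spa_glcm,61,none,NA,NA,92.50,93.33,91.80,92.56
rf,spectral,full_spectrum,200,none,NA,NA,87.50,88.33,86.89,87.60
rf,spectral,spa,33,none,NA,NA,88.33,89.16,87.70,88.42
rf,image,glcm,28,none,NA,NA,56.67,77.50,54.71,64.14
rf,fusion,full_spectrum_glcm,228,none,NA,NA,88.75,90.83,87.20,88.98
rf,fusion,spa_glcm,61,none,NA,NA,90.00,91.67,88.71,90.17
plsda,spectral,full_spectrum,200,none,NA,NA,85.83,90.00,90.00,90.00
plsda,spectral,spa,33,none,NA,NA,87.92,91.67,92.44,92.05
plsda,image,glcm,28,none,NA,NA,54.58,74.17,53.29,62.02
plsda,fusion,full_spectrum_glcm,228,none,NA,NA,89.17,92.50,86.72,89.52
plsda,fusion,spa_glcm,61,none,NA,NA,90.83,95.00,87.69,91.20
svm,fusion,spa_glcm,61,baseline,NA,NA,92.50,93.33,91.80,92.56
svm,fusion,spa_glcm,61,bwo,20.1626,0.2387,94.17,95.83,92.74,94.26
svm,fusion,spa_glcm,61,msbwo,18.4812,0.2198,95.00,96.67,93.55,95.08
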