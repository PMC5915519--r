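# Biodistribution of 211At-MABG in PC12 tumor-bearing mice (published group
# means +/- SD; %ID/g except thyroid, which is whole-organ %ID)
# decay_corrected: true
# n_per_timepoint: 5
organ,unit,mean_1h,sd_1h,mean_3h,sd_3h,mean_6h,sd_6h,mean_12h,sd_12h,mean_24h,sd_24h
Blood,pct_id_per_g,0.83,0.05,0.53,0.04,0.41,0.04,0.39,0.07,0.25,0.07
Liver,pct_id_per_g,9.79,1.44,5.30,0.57,3.17,0.30,2.22,0.34,1.05,0.32
Kidney,pct_id_per_g,2.88,0.23,1.83,0.06,1.65,0.19,1.24,0.30,0.77,0.15
Adrenals,pct_id_per_g,14.51,4.32,10.71,2.96,20.77,8.22,9.11,2.60,10.43,1.59
Intestine,pct_id_per_g,7.18,0.73,4.32,0.22,3.99,0.69,2.93,0.91,1.74,0.50
Spleen,pct_id_per_g,6.82,1.23,6.27,0.85,6.42,0.82,4.43,0.93,3.08,0.87
Pancreas,pct_id_per_g,7.62,0.86,3.89,0.84,2.22,0.49,1.68,0.45,0.95,0.21
Stomach,pct_id_per_g,3.41,1.04,2.41,0.44,5.08,1.08,6.71,0.76,3.39,1.10
Heart,pct_id_per_g,18.49,1.54,11.61,2.99,7.35,1.89,4.94,1.56,2.66,0.32
Lung,pct_id_per_g,8.49,2.00,4.57,1.21,2.68,1.22,2.67,0.63,1.64,0.77
Muscle,pct_id_per_g,2.15,0.14,1.59,0.28,1.20,0.17,0.88,0.21,0.42,0.17
Bone,pct_id_per_g,2.24,0.42,1.20,0.20,0.86,0.27,0.74,0.10,0.38,0.27
Brain,pct_id_per_g,0.13,0.04,0.08,0.01,0.04,0.01,0.07,0.03,0.03,0.01
PC12 tumor,pct_id_per_g,29.10,9.31,36.21,16.74,22.85,10.69,28.39,14.94,16.43,5.69
Thyroid,pct_id_per_organ,1.52,0.94,1.65,0.97,0.72,0.47,0.61,0.40,0.61,0.19
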