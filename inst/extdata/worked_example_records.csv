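"nodule_id","cohort","hu_u","hu_a","hu_v","ap_hu40","ap_hu70","ap_hu100","vp_hu40","vp_hu70","vp_hu100","ap_ic","vp_ic","ap_zeff","vp_zeff","ap_carotid_ic","vp_carotid_ic","ap_carotid_zeff","vp_carotid_zeff","calcification","enhanced_blurring","age_ge50","female","max_diameter_mm"
"example_benign","benign",60.7,186.6,140.4,327.2,160,60,267.4,150,60,5.28,3.77,8.2,9.4,14.2,5.5,10,10,"absent",FALSE,TRUE,TRUE,7
"example_malignant","malignant",65.9,139.9,148.3,265.6,140,65.9,274.8,150,66,2.81,3.02,7.9,9.5,9.9,4.2,10,10,"micro",TRUE,FALSE,TRUE,6
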