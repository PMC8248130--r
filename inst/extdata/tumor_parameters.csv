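cell_line,tumor,do_gy,n,dose_per_fraction_gy,fractions,alpha_ref,alpha_beta_ref,eqd2_ref,lq_eqd2_ref,clinical_alpha_beta,ref_do_gy,ref_n,group
Hypoxic Bell,Melanoma,6.50,2.0,20.0,1,0.17,3.3e2,29.3,50.0,10,,,srs
Oxic Bell,Melanoma,5.50,1.4,20.0,1,0.19,1.1e3,24.3,50.0,10,,,srs
Bell/MelH,Melanoma,1.68,3.5,20.0,1,0.60,2.1e5,41.9,50.0,10,,,srs
OMM-1,Metastatic melanoma,1.00,3.3,20.0,1,1.0,4.2e8,34.9,50.0,10,,,srs
OMM 2-2,Metastatic melanoma,0.81,4.4,20.0,1,1.2,2.5e10,37.4,50.0,10,,,srs
OMM 2-3,Metastatic melanoma,1.23,3.0,20.0,1,0.81,1.4e7,35.3,50.0,10,,,srs
OMM 2-6,Metastatic melanoma,1.11,4.2,20.0,1,0.90,4.6e7,41.9,50.0,10,,,srs
U373MG,Glioblastoma,1.73,4.2,20.0,1,0.58,1.1e5,48.5,50.0,10,,,srs
SW1573,Lung SCC,1.00,11.7,10.0,5,1.0,4.1e3,173.1,90.0,8,,,lung
In-vivo HX147,LCLC,3.00,3.2,10.0,5,0.38,1.0e2,86.6,90.0,8,,,lung
In-vivo HX149M,Variant SCLC,2.27,4.0,10.0,5,0.49,1.5e2,101.0,90.0,8,,,lung
In-vivo HX144,Lung AdC,2.20,4.0,10.0,5,0.50,1.6e2,101.2,90.0,8,,,lung
In-vivo HC12,Classic SCLC,1.70,4.5,10.0,5,0.62,3.7e2,108.5,90.0,8,,,lung
NHIK 3025 (n=1 subpop.),Cervical AdC,2.80,1.0,7.0,5,0.36,,35.0,49.6,10,,,hdrb
NHIK 3025 (n=58 subpop.),Cervical AdC,2.70,58.0,7.0,5,0.22,2.1e1,103.1,49.6,10,,,hdrb
NHIK 3025 (40Gy medium),Cervical AdC,2.71,2.8,7.0,5,0.43,5.9e1,51.1,49.6,10,,,hdrb
RL95-2,Primary EC,1.11,1.5,7.0,5,0.91,2.4e3,40.0,49.6,10,,,hdrb
KLE,Primary EC,1.12,2.6,7.0,5,0.91,7.4e2,49.6,49.6,10,,,hdrb
UM-EC-1,Primary EC,1.83,2.1,7.0,5,0.58,1.7e2,46.7,49.6,10,,,hdrb
UT-EC-1,Primary EC,2.40,1.5,7.0,5,0.44,2.0e2,40.6,49.6,10,,,hdrb
UM-EC-2,Metastatic EC,1.45,0.9,1.2,40,0.69,-6.1e1,48.7,52.8,10,,,hdrb
UT-EC-2,Metastatic EC,0.75,0.5,1.2,40,1.2,-1.1e1,52.6,52.8,10,,,hdrb
SKX,BOT SCC,2.55,0.2,1.2,60,0.42,-2.7e0,85.8,79.2,10,,,other
DaFu,H&N SCC,1.58,2.7,3.0,18,0.70,2.2e1,61.4,47.3,10,,,other
Hypoxic HT29,Colorectal AdC,3.24,15.0,5.0,5,0.17,1.9e1,39.6,32.5,8,,,other
Oxic HT29,Colorectal AdC,2.90,4.0,5.0,5,0.36,2.7e1,34.6,32.5,8,,,other
Plated HT29,Colorectal AdC,0.97,14.0,5.0,5,1.3,3.8e1,64.9,32.5,8,,,other
DU145,Prostate AdC,2.20,2.8,7.4,5,0.51,9.0e1,56.4,77.0,3,,,prostate
CP3,Prostate AdC,1.08,20.0,7.4,5,1.0,1.2e2,162.9,77.0,3,,,prostate
MDA-MB-231 (gamma),Breast cancer,1.49,3.8,2.66,16,0.72,1.5e1,48.1,44.9,10,,,other
MDA-MB-231 (alpha),Breast cancer,0.80,1.0,2.50,5,1.3,,56.2,13.0,10,1.49,3.8,other
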