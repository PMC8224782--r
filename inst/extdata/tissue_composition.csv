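tissue,f_ew,f_iw,f_nl,f_np,ap_mg_g,alb_ratio,ph_iw,provenance
adipose,0.135,0.017,0.853,0.0016,0.40,0.049,7.0,Rodgers & Rowland 2006 compilation
bone,0.100,0.346,0.017,0.0017,0.67,0.100,7.0,Rodgers & Rowland 2006 compilation
brain,0.162,0.620,0.039,0.0015,0.40,0.048,7.0,Rodgers & Rowland 2006 compilation
gut_wall,0.282,0.475,0.038,0.0125,2.41,0.158,7.0,Rodgers & Rowland 2006 compilation
heart,0.320,0.456,0.014,0.0111,2.25,0.157,7.0,Rodgers & Rowland 2006 compilation
kidney,0.273,0.483,0.012,0.0240,5.03,0.130,7.0,Rodgers & Rowland 2006 compilation
liver,0.161,0.573,0.014,0.0240,4.56,0.086,7.0,Rodgers & Rowland 2006 compilation
lung,0.336,0.446,0.022,0.0128,3.91,0.212,7.0,Rodgers & Rowland 2006 compilation
muscle,0.118,0.630,0.010,0.0072,1.53,0.064,7.0,Rodgers & Rowland 2006 compilation
skin,0.382,0.291,0.060,0.0044,1.32,0.277,7.0,Rodgers & Rowland 2006 compilation
spleen,0.207,0.579,0.0077,0.0113,3.18,0.097,7.0,Rodgers & Rowland 2006 compilation
pancreas,0.120,0.664,0.041,0.0093,1.67,0.060,7.0,Rodgers & Rowland 2006 compilation
stomach,0.320,0.470,0.038,0.0125,2.41,0.158,7.0,gut-like surrogate (documented assumption)
rest,0.200,0.550,0.040,0.0100,1.50,0.100,7.0,volume-weighted generic soft tissue (documented assumption)
blood_cells,0.000,0.603,0.0017,0.0029,0.50,0.000,7.22,Rodgers & Rowland 2005 blood cell composition
plasma,1.000,0.000,0.0023,0.0013,0.00,1.000,7.4,Rodgers & Rowland 2006 plasma composition
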