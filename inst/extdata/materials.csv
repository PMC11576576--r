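name,category,density_g_cm3,H,C,N,O,Na,Mg,Al,Si,P,S,Cl,Ar,K,Ca,Ti,Fe
water,soft,1,0.111894,0,0,0.888106,0,0,0,0,0,0,0,0,0,0,0,0
air,air,0.0012,0,0,0.755,0.232,0,0,0,0,0,0,0,0.013,0,0,0,0
brain_white_matter,soft,1.04,0.106,0.194,0.025,0.661,0.002,0,0,0,0.004,0.002,0.003,0,0.003,0,0,0
brain_gray_matter,soft,1.04,0.107,0.095,0.018,0.767,0.002,0,0,0,0.003,0.002,0.003,0,0.003,0,0,0
brain_whole,soft,1.04,0.107,0.145,0.022,0.712,0.002,0,0,0,0.004,0.002,0.003,0,0.003,0,0,0
skull_cortical_bone,bone,1.92,0.034,0.155,0.042,0.435,0.001,0.002,0,0,0.103,0.003,0,0,0,0.225,0,0
adipose,soft,0.95,0.114,0.598,0.007,0.278,0.001,0,0,0,0,0.001,0.001,0,0,0,0,0
skin,soft,1.09,0.1,0.204,0.042,0.645,0.002,0,0,0,0.001,0.002,0.003,0,0.001,0,0,0
muscle_skeletal,soft,1.05,0.102,0.143,0.034,0.71,0.001,0,0,0,0.002,0.003,0.001,0,0.004,0,0,0
liver,soft,1.06,0.102,0.139,0.03,0.716,0.002,0,0,0,0.003,0.003,0.002,0,0.003,0,0,0
blood_whole,soft,1.06,0.102,0.11,0.033,0.745,0.001,0,0,0,0.001,0.002,0.003,0,0.002,0,0,0.001
kidney,soft,1.05,0.103,0.132,0.03,0.724,0.002,0,0,0,0.002,0.002,0.002,0,0.002,0.001,0,0
spleen,soft,1.06,0.103,0.113,0.032,0.741,0.001,0,0,0,0.003,0.002,0.002,0,0.003,0,0,0
pancreas,soft,1.04,0.106,0.169,0.022,0.694,0.002,0,0,0,0.002,0.001,0.002,0,0.002,0,0,0
eye_lens,soft,1.07,0.096,0.195,0.057,0.646,0.001,0,0,0,0.001,0.003,0.001,0,0,0,0,0
cartilage,soft,1.1,0.096,0.099,0.022,0.744,0.005,0,0,0,0.022,0.009,0.003,0,0,0,0,0
lung_inflated,lung,0.26,0.103,0.105,0.031,0.749,0.002,0,0,0,0.002,0.003,0.003,0,0.002,0,0,0
spongiosa,bone,1.18,0.085,0.404,0.028,0.367,0.001,0.001,0,0,0.034,0.002,0.002,0,0.001,0.074,0,0.001
bone_femur,bone,1.33,0.07,0.345,0.028,0.368,0.001,0.001,0,0,0.055,0.002,0.001,0,0.001,0.128,0,0
bone_cranium,bone,1.61,0.05,0.212,0.04,0.435,0.001,0.002,0,0,0.081,0.003,0,0,0,0.176,0,0
polyethylene,plastic,0.94,0.143716,0.856284,0,0,0,0,0,0,0,0,0,0,0,0,0,0
pvc,plastic,1.4,0.048382,0.38436,0,0,0,0,0,0,0,0,0.567258,0,0,0,0,0
insert_lung300,lung,0.3,0.085,0.596,0.02,0.181,0,0.112,0,0.006,0,0,0,0,0,0,0,0
insert_adipose,soft,0.94,0.091,0.723,0.022,0.163,0,0,0,0,0,0,0.001,0,0,0,0,0
insert_breast,soft,0.99,0.086,0.701,0.023,0.179,0,0,0,0,0,0,0.001,0,0,0.01,0,0
insert_solid_water,soft,1.015,0.08,0.672,0.024,0.199,0,0,0,0,0,0,0.002,0,0,0.023,0,0
insert_muscle,soft,1.05,0.081,0.671,0.026,0.199,0,0,0,0,0,0,0.001,0,0,0.022,0,0
insert_liver,soft,1.09,0.081,0.67,0.025,0.2,0,0,0,0,0,0,0.001,0,0,0.023,0,0
insert_inner_bone,bone,1.14,0.067,0.556,0.02,0.235,0,0,0,0,0.032,0,0.001,0,0,0.089,0,0
insert_b200,bone,1.15,0.066,0.555,0.02,0.237,0,0,0,0,0.032,0,0.001,0,0,0.089,0,0
insert_cb2_30,bone,1.33,0.067,0.535,0.021,0.256,0,0,0,0,0,0,0.001,0,0,0.12,0,0
insert_cb2_50,bone,1.56,0.048,0.416,0.015,0.32,0,0,0,0,0,0,0.001,0,0,0.2,0,0
insert_cortical,bone,1.82,0.034,0.314,0.018,0.365,0,0,0,0,0,0,0.001,0,0,0.268,0,0
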