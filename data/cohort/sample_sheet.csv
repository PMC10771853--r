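sample_id,das28_baseline,das28_followup,age,sex,smoking,mtx,response
S001,4.94,5.19,57,M,0,0,non_responder
S002,4.68,2.83,59.9,F,0,1,responder
S003,3.7,5.89,36.1,M,0,1,non_responder
S004,3.07,1.91,56.4,F,0,1,responder
S005,5.02,2.16,50.3,F,0,1,responder
S006,4.84,0.74,53.4,F,1,0,responder
S007,5.96,4.62,60.4,M,1,1,responder
S008,3.85,5.98,65,M,0,1,non_responder
S009,4.96,5.91,54.6,F,0,0,non_responder
S010,3.3,2.57,66,M,1,0,responder
S011,4.57,4.38,60.3,M,1,1,non_responder
S012,4.78,0.46,44.5,F,1,1,responder
S013,4.92,4.74,76.1,M,0,1,non_responder
S014,6.31,4.28,57.7,F,1,1,responder
S015,5.28,5.33,66,F,1,1,non_responder
S016,4.03,4.05,44.3,F,0,1,non_responder
S017,4.63,2.78,40.9,F,0,1,responder
S018,4.49,4.87,54.8,F,1,1,non_responder
S019,4.6,4.09,42.2,F,0,1,non_responder
S020,5.64,3.09,52.9,F,0,1,responder
S021,6.52,5.66,59.4,F,0,0,non_responder
S022,6.94,6.5,72.5,F,0,1,non_responder
S023,5.01,3.4,53.6,F,0,0,responder
S024,7.12,4.13,29,F,0,0,responder
S025,5.27,6.81,30.3,M,0,1,non_responder
S026,4.34,2.48,62.4,F,1,1,responder
S027,3.86,2.86,56.6,F,0,1,responder
S028,4.51,2.44,53.7,F,1,1,responder
S029,4.01,2.28,49.3,F,0,1,responder
S030,5.04,1.82,56.2,F,1,1,responder
S031,5.57,1.34,42.6,F,0,1,responder
S032,6.96,3.25,39,F,0,1,responder
S033,4.52,4.47,51.7,F,1,1,non_responder
S034,3.63,4.2,74.2,F,0,1,non_responder
S035,1.83,0.62,57.8,F,0,0,responder
S036,6.53,6.7,59,F,0,0,non_responder
S037,6.98,1.66,54.4,F,0,1,responder
S038,4.8,2.59,54.1,M,0,0,responder
S039,5.06,2.69,55.2,M,0,0,responder
S040,3.43,4.12,47.7,M,1,1,non_responder
S041,5.25,5.58,64.1,M,1,0,non_responder
S042,5.6,5.07,64.9,F,1,0,non_responder
S043,5.55,5.41,54,F,1,1,non_responder
S044,2.74,1.35,62.2,F,0,1,responder
S045,4.83,1.45,49.3,F,1,0,responder
S046,4.7,1.46,48.9,F,0,1,responder
S047,6.03,5.96,58.8,F,1,1,non_responder
S048,3.62,2.63,69.2,F,0,1,responder
S049,5.36,5.16,60.4,F,0,1,non_responder
S050,3.42,4.63,59.2,M,0,1,non_responder
S051,3.9,1.15,50.5,F,1,0,responder
S052,5.43,4.94,49.3,M,0,0,non_responder
S053,3.23,5.89,65.3,F,1,0,non_responder
S054,5.62,3.73,43.9,F,0,1,responder
S055,4.56,3.06,45.3,F,0,0,responder
S056,7.4,6.21,45.8,F,0,1,non_responder
S057,5.49,2.39,52.7,F,0,0,responder
S058,3.88,2.28,54.2,M,0,1,responder
S059,5.82,6.72,70,F,0,0,non_responder
S060,4.96,0.24,32.4,F,0,1,responder
S061,5.23,3.6,39.4,F,0,0,responder
S062,5.11,5.01,58.1,M,1,0,non_responder
S063,4.61,4.15,63.5,F,0,1,non_responder
S064,5.23,6,50.1,F,0,1,non_responder
S065,6.62,7.24,48.8,F,1,1,non_responder
S066,1.63,0,67.7,F,0,0,responder
S067,5.2,3.55,48.6,F,0,0,responder
S068,4.91,2.72,49.6,F,0,1,responder
S069,7.19,6.66,22.8,M,1,1,non_responder
S070,4.94,4.51,34.8,F,0,0,non_responder
S071,5.3,0,41.8,F,0,1,responder
S072,4.45,1.95,47.1,F,0,1,responder
S073,6.66,6.76,30.8,M,1,1,non_responder
S074,5.76,3.91,65.9,F,0,1,responder
S075,4.64,2.6,47.7,F,0,0,responder
S076,4.56,4.31,62,F,0,1,non_responder
S077,6.11,1.42,44.4,F,0,1,responder
S078,5.06,6.1,60.9,F,0,0,non_responder
S079,4.75,4.44,62.1,F,0,1,non_responder
S080,7,1.72,54.5,F,0,1,responder
S081,4.65,5.33,63.6,F,1,0,non_responder
S082,4.7,3.48,47.6,F,0,1,responder
S083,5.93,2.36,40.2,F,0,1,responder
S084,5.49,0.32,43.5,F,0,1,responder
S085,5.19,4.76,54.3,F,1,1,non_responder
S086,4.36,4.76,43.3,F,0,0,non_responder
S087,5.27,5.38,70.3,F,1,0,non_responder
S088,5.12,2.87,43.3,F,0,1,responder
S089,3.92,4.37,47.3,F,0,1,non_responder
S090,6.38,5.43,58.6,F,0,0,non_responder
S091,5.11,2.92,71.7,F,0,1,responder
S092,2.82,1.75,55.6,M,0,1,responder
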