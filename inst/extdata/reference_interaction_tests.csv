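parameter,delta_r2,df1,df2,f_value,p_uncorrected,p_fdr_published
duration_MS1,0.004,1,329,1.548,0.214,0.278
duration_MS2,0.046,1,329,17.691,3.354289e-05,0.005
duration_MS3,0.007,1,329,2.440,0.119,0.226
duration_MS4,0.007,1,329,2.411,0.122,0.226
occurrence_MS1,0.014,1,329,5.090,0.024,0.082
occurrence_MS2,0.002,1,329,0.060,0.807,0.807
occurrence_MS3,0.022,1,329,8.061,0.005,0.030
occurrence_MS4,0.012,1,329,4.372,0.037,0.111
contribution_MS1,0.007,1,329,2.397,0.123,0.226
contribution_MS2,0.026,1,329,9.598,0.002,0.024
contribution_MS3,0.003,1,329,1.122,0.290,0.316
contribution_MS4,0.001,1,329,0.299,0.585,0.610
transition_MS1_MS2,0.005,1,329,1.623,0.204,0.278
transition_MS1_MS3,0.004,1,329,1.274,0.260,0.297
transition_MS1_MS4,0.016,1,329,5.887,0.016,0.064
transition_MS2_MS1,0.004,1,329,1.514,0.220,0.278
transition_MS2_MS3,0.004,1,329,1.295,0.256,0.297
transition_MS2_MS4,0.023,1,329,8.652,0.004,0.030
transition_MS3_MS1,0.009,1,329,3.178,0.076,0.182
transition_MS3_MS2,0.006,1,329,2.202,0.139,0.226
transition_MS3_MS4,0.005,1,329,1.633,0.202,0.278
transition_MS4_MS1,0.010,1,329,3.739,0.054,0.144
transition_MS4_MS2,0.018,1,329,6.766,0.009,0.047
transition_MS4_MS3,0.006,1,329,2.179,0.141,0.226
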