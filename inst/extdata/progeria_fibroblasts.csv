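cell_line,progeria,sex,age,dnam_age,accel
PSADFN086,NonClassic,m,0.58,0.39,-3.49
PSADFN257,NonClassic,m,1.83,4.44,-0.51
PSADFN257.replicate,NonClassic,m,1.8,4.84,-0.08
PSADFN317,NonClassic,m,3.8,8.86,2.23
PSADFN318,NonClassic,m,0.4,7.48,3.75
PSADFN392,NonClassic,m,7.3,21.61,11.99
HGADFN003,Classic,m,2,3.39,-1.70
HGADFN169,Classic,m,8.5,23.73,13.08
HGADFN143,Classic,m,8.8,15.61,4.71
HGADFN167,Classic,m,8.4,17.88,7.32
HGADFN271,Classic,m,1.3,10.73,6.24
HGADFN164,Classic,f,4.66,10.64,3.28
HGADFN178,Classic,f,6.92,4.36,-4.93
HGADFN122,Classic,f,5,6.96,-0.70
HGADFN127,Classic,f,3.8,2.10,-4.53
HGADFN155,Classic,f,1.1,0.59,-3.73
HGADFN188,Classic,f,2.3,1.23,-4.11
HGADFN367,Classic,f,3,17.10,11.16
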