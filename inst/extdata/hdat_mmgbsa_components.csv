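system_id,e_ele,e_vdw,g_pol,g_nonpol,claimed_total,sd,ic50_nm
benztropine-hDAT,-115.81,-41.92,129.01,-5.39,-34.12,2.88,312
JHW007-hDAT,-126.38,-54.98,141.36,-7.04,-47.03,2.68,24.6
S-modafinil-hDAT,-25.52,-36.22,37.51,-5.47,-29.69,3.26,6660
compound4-hDAT,-111.41,-40.39,129.99,-5.44,-27.25,3.34,753
compound14-hDAT,-129.14,-35.08,140.97,-4.46,-27.71,3.43,542
compound19-hDAT,-99.11,-38.22,115.75,-5.27,-26.84,2.70,1210
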