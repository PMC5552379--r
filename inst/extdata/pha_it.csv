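# Phalpha1beta, intrathecal, capsaicin test; per-animal dose (nmol/site) and %MPE.
# Curation: the 13th source row (response 50.00) prints dose 0.0003 with log -2.52;
# the log and the 0.003 block it opens show the dose is 0.003, stored as such here.
regimen,dose,unit,response
Pha1b_it,0.0003,nmol/site,39.54
Pha1b_it,0.0003,nmol/site,-25.58
Pha1b_it,0.0003,nmol/site,31.40
Pha1b_it,0.0003,nmol/site,-4.65
Pha1b_it,0.0003,nmol/site,41.29
Pha1b_it,0.0003,nmol/site,13.11
Pha1b_it,0.0003,nmol/site,4.50
Pha1b_it,0.0003,nmol/site,-0.98
Pha1b_it,0.0003,nmol/site,13.82
Pha1b_it,0.0003,nmol/site,12.88
Pha1b_it,0.0003,nmol/site,-1.17
Pha1b_it,0.0003,nmol/site,20.38
Pha1b_it,0.003,nmol/site,50.00
Pha1b_it,0.003,nmol/site,24.63
Pha1b_it,0.003,nmol/site,39.55
Pha1b_it,0.003,nmol/site,34.18
Pha1b_it,0.003,nmol/site,65.40
Pha1b_it,0.003,nmol/site,20.37
Pha1b_it,0.003,nmol/site,24.07
Pha1b_it,0.003,nmol/site,17.44
Pha1b_it,0.003,nmol/site,23.26
Pha1b_it,0.003,nmol/site,20.93
Pha1b_it,0.003,nmol/site,27.20
Pha1b_it,0.003,nmol/site,63.47
Pha1b_it,0.003,nmol/site,42.86
Pha1b_it,0.003,nmol/site,37.24
Pha1b_it,0.01,nmol/site,19.84
Pha1b_it,0.01,nmol/site,-30.95
Pha1b_it,0.01,nmol/site,47.76
Pha1b_it,0.01,nmol/site,50.00
Pha1b_it,0.01,nmol/site,96.27
Pha1b_it,0.01,nmol/site,40.08
Pha1b_it,0.01,nmol/site,33.33
Pha1b_it,0.01,nmol/site,26.58
Pha1b_it,0.01,nmol/site,26.19
Pha1b_it,0.01,nmol/site,41.67
Pha1b_it,0.01,nmol/site,37.96
Pha1b_it,0.01,nmol/site,35.19
Pha1b_it,0.01,nmol/site,43.52
Pha1b_it,0.01,nmol/site,43.52
Pha1b_it,0.01,nmol/site,45.37
Pha1b_it,0.01,nmol/site,50.00
Pha1b_it,0.10,nmol/site,50.00
Pha1b_it,0.10,nmol/site,36.51
Pha1b_it,0.10,nmol/site,39.55
Pha1b_it,0.10,nmol/site,69.40
Pha1b_it,0.10,nmol/site,68.66
Pha1b_it,0.10,nmol/site,29.11
Pha1b_it,0.10,nmol/site,40.93
Pha1b_it,0.10,nmol/site,28.27
Pha1b_it,0.10,nmol/site,33.33
Pha1b_it,0.10,nmol/site,58.33
Pha1b_it,0.10,nmol/site,42.59
Pha1b_it,0.10,nmol/site,66.67
Pha1b_it,0.10,nmol/site,55.56
Pha1b_it,0.10,nmol/site,59.26
Pha1b_it,0.10,nmol/site,69.44
Pha1b_it,0.30,nmol/site,57.14
Pha1b_it,0.30,nmol/site,-3.97
Pha1b_it,0.30,nmol/site,58.21
Pha1b_it,0.30,nmol/site,71.64
Pha1b_it,0.30,nmol/site,67.91
Pha1b_it,0.30,nmol/site,45.15
Pha1b_it,0.30,nmol/site,51.06
Pha1b_it,0.30,nmol/site,29.96
Pha1b_it,0.30,nmol/site,36.91
Pha1b_it,0.30,nmol/site,60.71
Pha1b_it,0.30,nmol/site,51.85
Pha1b_it,0.30,nmol/site,75.93
Pha1b_it,0.30,nmol/site,55.56
Pha1b_it,0.30,nmol/site,62.96
Pha1b_it,0.30,nmol/site,77.78
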