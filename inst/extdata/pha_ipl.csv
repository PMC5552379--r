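# Phalpha1beta, intraplantar, capsaicin test; per-animal dose (nmol/site) and %MPE.
regimen,dose,unit,response
Pha1b_ipl,0.01,nmol/site,19.51
Pha1b_ipl,0.01,nmol/site,27.44
Pha1b_ipl,0.01,nmol/site,46.34
Pha1b_ipl,0.01,nmol/site,0.33
Pha1b_ipl,0.01,nmol/site,6.23
Pha1b_ipl,0.01,nmol/site,-36.30
Pha1b_ipl,0.01,nmol/site,20.49
Pha1b_ipl,0.01,nmol/site,12.31
Pha1b_ipl,0.03,nmol/site,18.90
Pha1b_ipl,0.03,nmol/site,31.71
Pha1b_ipl,0.03,nmol/site,18.69
Pha1b_ipl,0.03,nmol/site,44.92
Pha1b_ipl,0.03,nmol/site,7.54
Pha1b_ipl,0.03,nmol/site,30.51
Pha1b_ipl,0.03,nmol/site,30.51
Pha1b_ipl,0.03,nmol/site,-15.59
Pha1b_ipl,0.10,nmol/site,64.63
Pha1b_ipl,0.10,nmol/site,26.22
Pha1b_ipl,0.10,nmol/site,50.61
Pha1b_ipl,0.10,nmol/site,48.17
Pha1b_ipl,0.10,nmol/site,8.20
Pha1b_ipl,0.10,nmol/site,14.10
Pha1b_ipl,0.10,nmol/site,35.74
Pha1b_ipl,0.10,nmol/site,37.05
Pha1b_ipl,0.10,nmol/site,25.84
Pha1b_ipl,0.10,nmol/site,29.18
Pha1b_ipl,0.10,nmol/site,38.53
Pha1b_ipl,0.30,nmol/site,54.27
Pha1b_ipl,0.30,nmol/site,44.51
Pha1b_ipl,0.30,nmol/site,43.61
Pha1b_ipl,0.30,nmol/site,20.00
Pha1b_ipl,0.30,nmol/site,30.49
Pha1b_ipl,0.30,nmol/site,45.88
Pha1b_ipl,0.30,nmol/site,55.23
Pha1b_ipl,0.30,nmol/site,5.12
Pha1b_ipl,0.50,nmol/site,67.68
Pha1b_ipl,0.50,nmol/site,68.29
Pha1b_ipl,0.50,nmol/site,62.20
Pha1b_ipl,0.50,nmol/site,62.80
Pha1b_ipl,0.50,nmol/site,65.85
Pha1b_ipl,0.50,nmol/site,30.49
Pha1b_ipl,0.50,nmol/site,35.08
Pha1b_ipl,0.50,nmol/site,41.64
Pha1b_ipl,0.50,nmol/site,41.64
Pha1b_ipl,0.50,nmol/site,41.87
Pha1b_ipl,0.50,nmol/site,58.57
Pha1b_ipl,0.50,nmol/site,56.57
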