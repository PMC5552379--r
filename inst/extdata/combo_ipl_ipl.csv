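# Fixed-ratio mixture of SB366791 + Phalpha1beta, both intraplantar.
# Dose is the composed pair total (nmol/site); response is %MPE.
regimen,dose,unit,response
combo_ipl_ipl,0.013,nmol/site,34.00
combo_ipl_ipl,0.013,nmol/site,24.85
combo_ipl_ipl,0.013,nmol/site,3.93
combo_ipl_ipl,0.013,nmol/site,27.50
combo_ipl_ipl,0.013,nmol/site,-19.89
combo_ipl_ipl,0.013,nmol/site,-2.37
combo_ipl_ipl,0.013,nmol/site,32.66
combo_ipl_ipl,0.013,nmol/site,-63.64
combo_ipl_ipl,0.013,nmol/site,25.00
combo_ipl_ipl,0.013,nmol/site,29.09
combo_ipl_ipl,0.013,nmol/site,-20.00
combo_ipl_ipl,0.013,nmol/site,25.68
combo_ipl_ipl,0.038,nmol/site,36.81
combo_ipl_ipl,0.038,nmol/site,43.56
combo_ipl_ipl,0.038,nmol/site,26.38
combo_ipl_ipl,0.038,nmol/site,30.86
combo_ipl_ipl,0.038,nmol/site,29.27
combo_ipl_ipl,0.038,nmol/site,44.01
combo_ipl_ipl,0.038,nmol/site,26.09
combo_ipl_ipl,0.038,nmol/site,39.23
combo_ipl_ipl,0.038,nmol/site,38.14
combo_ipl_ipl,0.038,nmol/site,27.05
combo_ipl_ipl,0.038,nmol/site,20.23
combo_ipl_ipl,0.038,nmol/site,16.82
combo_ipl_ipl,0.115,nmol/site,15.95
combo_ipl_ipl,0.115,nmol/site,46.01
combo_ipl_ipl,0.115,nmol/site,27.61
combo_ipl_ipl,0.115,nmol/site,50.10
combo_ipl_ipl,0.115,nmol/site,44.09
combo_ipl_ipl,0.115,nmol/site,28.09
combo_ipl_ipl,0.115,nmol/site,32.22
combo_ipl_ipl,0.115,nmol/site,46.37
combo_ipl_ipl,0.115,nmol/site,26.09
combo_ipl_ipl,0.115,nmol/site,41.42
combo_ipl_ipl,0.115,nmol/site,37.59
combo_ipl_ipl,0.115,nmol/site,31.82
combo_ipl_ipl,0.115,nmol/site,25.00
combo_ipl_ipl,0.115,nmol/site,16.00
combo_ipl_ipl,0.115,nmol/site,16.82
combo_ipl_ipl,0.346,nmol/site,51.53
combo_ipl_ipl,0.346,nmol/site,52.15
combo_ipl_ipl,0.346,nmol/site,31.90
combo_ipl_ipl,0.346,nmol/site,54.31
combo_ipl_ipl,0.346,nmol/site,51.30
combo_ipl_ipl,0.346,nmol/site,59.12
combo_ipl_ipl,0.346,nmol/site,40.01
combo_ipl_ipl,0.346,nmol/site,33.99
combo_ipl_ipl,0.346,nmol/site,46.90
combo_ipl_ipl,0.346,nmol/site,60.04
combo_ipl_ipl,0.346,nmol/site,74.27
combo_ipl_ipl,0.346,nmol/site,35.91
combo_ipl_ipl,0.346,nmol/site,30.45
combo_ipl_ipl,0.346,nmol/site,36.59
combo_ipl_ipl,0.346,nmol/site,15.45
combo_ipl_ipl,1.038,nmol/site,52.76
combo_ipl_ipl,1.038,nmol/site,60.12
combo_ipl_ipl,1.038,nmol/site,53.99
combo_ipl_ipl,1.038,nmol/site,86.77
combo_ipl_ipl,1.038,nmol/site,49.50
combo_ipl_ipl,1.038,nmol/site,63.93
combo_ipl_ipl,1.038,nmol/site,54.03
combo_ipl_ipl,1.038,nmol/site,45.78
combo_ipl_ipl,1.038,nmol/site,49.90
combo_ipl_ipl,1.038,nmol/site,49.64
combo_ipl_ipl,1.038,nmol/site,65.51
combo_ipl_ipl,1.038,nmol/site,59.49
combo_ipl_ipl,1.038,nmol/site,45.45
combo_ipl_ipl,1.038,nmol/site,45.45
combo_ipl_ipl,1.038,nmol/site,16.14
combo_ipl_ipl,1.038,nmol/site,50.23
combo_ipl_ipl,3.114,nmol/site,54.60
combo_ipl_ipl,3.114,nmol/site,63.80
combo_ipl_ipl,3.114,nmol/site,66.26
combo_ipl_ipl,3.114,nmol/site,69.94
combo_ipl_ipl,3.114,nmol/site,61.52
combo_ipl_ipl,3.114,nmol/site,65.13
combo_ipl_ipl,3.114,nmol/site,61.10
combo_ipl_ipl,3.114,nmol/site,58.74
combo_ipl_ipl,3.114,nmol/site,68.17
combo_ipl_ipl,3.114,nmol/site,67.70
combo_ipl_ipl,3.114,nmol/site,68.25
combo_ipl_ipl,3.114,nmol/site,72.08
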