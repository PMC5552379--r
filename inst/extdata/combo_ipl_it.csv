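# Fixed-ratio mixture of SB366791 (intraplantar) + Phalpha1beta (intrathecal).
# Dose is the composed pair total (nmol/site); response is %MPE.
regimen,dose,unit,response
combo_ipl_it,0.022,nmol/site,2.00
combo_ipl_it,0.022,nmol/site,-33.77
combo_ipl_it,0.022,nmol/site,32.95
combo_ipl_it,0.022,nmol/site,-34.79
combo_ipl_it,0.022,nmol/site,29.24
combo_ipl_it,0.022,nmol/site,32.19
combo_ipl_it,0.022,nmol/site,49.14
combo_ipl_it,0.022,nmol/site,5.42
combo_ipl_it,0.022,nmol/site,23.73
combo_ipl_it,0.022,nmol/site,37.13
combo_ipl_it,0.022,nmol/site,52.16
combo_ipl_it,0.022,nmol/site,34.40
combo_ipl_it,0.066,nmol/site,15.30
combo_ipl_it,0.066,nmol/site,51.72
combo_ipl_it,0.066,nmol/site,50.92
combo_ipl_it,0.066,nmol/site,25.35
combo_ipl_it,0.066,nmol/site,-29.95
combo_ipl_it,0.066,nmol/site,34.40
combo_ipl_it,0.066,nmol/site,39.56
combo_ipl_it,0.066,nmol/site,49.14
combo_ipl_it,0.066,nmol/site,24.75
combo_ipl_it,0.066,nmol/site,32.88
combo_ipl_it,0.066,nmol/site,34.40
combo_ipl_it,0.066,nmol/site,26.88
combo_ipl_it,0.200,nmol/site,27.18
combo_ipl_it,0.200,nmol/site,5.01
combo_ipl_it,0.200,nmol/site,54.88
combo_ipl_it,0.200,nmol/site,14.98
combo_ipl_it,0.200,nmol/site,-2.30
combo_ipl_it,0.200,nmol/site,50.23
combo_ipl_it,0.200,nmol/site,52.09
combo_ipl_it,0.200,nmol/site,46.93
combo_ipl_it,0.200,nmol/site,68.30
combo_ipl_it,0.200,nmol/site,31.86
combo_ipl_it,0.200,nmol/site,40.00
combo_ipl_it,0.200,nmol/site,59.32
combo_ipl_it,0.200,nmol/site,35.08
combo_ipl_it,0.200,nmol/site,34.00
combo_ipl_it,0.200,nmol/site,55.58
combo_ipl_it,0.600,nmol/site,62.01
combo_ipl_it,0.600,nmol/site,37.47
combo_ipl_it,0.600,nmol/site,35.88
combo_ipl_it,0.600,nmol/site,70.28
combo_ipl_it,0.600,nmol/site,54.38
combo_ipl_it,0.600,nmol/site,53.69
combo_ipl_it,0.600,nmol/site,54.30
combo_ipl_it,0.600,nmol/site,53.56
combo_ipl_it,0.600,nmol/site,65.36
combo_ipl_it,0.600,nmol/site,41.02
combo_ipl_it,0.600,nmol/site,36.95
combo_ipl_it,0.600,nmol/site,59.32
combo_ipl_it,0.600,nmol/site,52.16
combo_ipl_it,0.600,nmol/site,41.23
combo_ipl_it,0.600,nmol/site,56.95
combo_ipl_it,1.800,nmol/site,81.00
combo_ipl_it,1.800,nmol/site,71.50
combo_ipl_it,1.800,nmol/site,52.51
combo_ipl_it,1.800,nmol/site,71.66
combo_ipl_it,1.800,nmol/site,57.14
combo_ipl_it,1.800,nmol/site,59.22
combo_ipl_it,1.800,nmol/site,74.20
combo_ipl_it,1.800,nmol/site,54.30
combo_ipl_it,1.800,nmol/site,67.57
combo_ipl_it,1.800,nmol/site,52.20
combo_ipl_it,1.800,nmol/site,43.05
combo_ipl_it,1.800,nmol/site,63.39
combo_ipl_it,1.800,nmol/site,44.65
combo_ipl_it,1.800,nmol/site,48.75
combo_ipl_it,1.800,nmol/site,63.78
combo_ipl_it,5.400,nmol/site,77.88
combo_ipl_it,5.400,nmol/site,57.83
combo_ipl_it,5.400,nmol/site,68.89
combo_ipl_it,5.400,nmol/site,76.41
combo_ipl_it,5.400,nmol/site,56.51
combo_ipl_it,5.400,nmol/site,69.78
combo_ipl_it,5.400,nmol/site,65.42
combo_ipl_it,5.400,nmol/site,52.20
combo_ipl_it,5.400,nmol/site,67.46
combo_ipl_it,5.400,nmol/site,57.63
combo_ipl_it,5.400,nmol/site,61.05
combo_ipl_it,5.400,nmol/site,65.15
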