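# SB366791, intraplantar, capsaicin test; per-animal dose (nmol/site) and %MPE.
# One source row prints the log of dose 0.10 as +1.00 (response 64.31); the dose
# column is authoritative and logs are always recomputed, so no correction is needed.
regimen,dose,unit,response
SB366791_ipl,0.10,nmol/site,8.86
SB366791_ipl,0.10,nmol/site,-14.77
SB366791_ipl,0.10,nmol/site,-41.77
SB366791_ipl,0.10,nmol/site,38.29
SB366791_ipl,0.10,nmol/site,37.43
SB366791_ipl,0.10,nmol/site,-22.57
SB366791_ipl,0.10,nmol/site,-23.58
SB366791_ipl,0.10,nmol/site,0.81
SB366791_ipl,0.10,nmol/site,-10.76
SB366791_ipl,0.10,nmol/site,-0.63
SB366791_ipl,0.10,nmol/site,-13.83
SB366791_ipl,0.10,nmol/site,64.31
SB366791_ipl,0.10,nmol/site,48.42
SB366791_ipl,0.10,nmol/site,18.18
SB366791_ipl,0.40,nmol/site,-13.08
SB366791_ipl,0.40,nmol/site,-23.21
SB366791_ipl,0.40,nmol/site,4.64
SB366791_ipl,0.40,nmol/site,9.14
SB366791_ipl,0.40,nmol/site,36.57
SB366791_ipl,0.40,nmol/site,27.14
SB366791_ipl,0.40,nmol/site,45.80
SB366791_ipl,0.40,nmol/site,33.33
SB366791_ipl,0.40,nmol/site,0.27
SB366791_ipl,0.40,nmol/site,12.03
SB366791_ipl,0.40,nmol/site,59.49
SB366791_ipl,1.00,nmol/site,-25.75
SB366791_ipl,1.00,nmol/site,18.16
SB366791_ipl,1.00,nmol/site,12.20
SB366791_ipl,1.00,nmol/site,-1.90
SB366791_ipl,1.00,nmol/site,17.72
SB366791_ipl,1.00,nmol/site,25.32
SB366791_ipl,1.00,nmol/site,2.53
SB366791_ipl,1.00,nmol/site,5.06
SB366791_ipl,1.00,nmol/site,-19.61
SB366791_ipl,1.00,nmol/site,6.43
SB366791_ipl,1.00,nmol/site,-12.06
SB366791_ipl,1.00,nmol/site,50.79
SB366791_ipl,1.00,nmol/site,29.37
SB366791_ipl,1.00,nmol/site,15.08
SB366791_ipl,1.00,nmol/site,44.44
SB366791_ipl,1.00,nmol/site,31.75
SB366791_ipl,2.00,nmol/site,26.58
SB366791_ipl,2.00,nmol/site,70.46
SB366791_ipl,2.00,nmol/site,53.59
SB366791_ipl,2.00,nmol/site,22.86
SB366791_ipl,2.00,nmol/site,40.86
SB366791_ipl,2.00,nmol/site,13.43
SB366791_ipl,2.00,nmol/site,13.28
SB366791_ipl,2.00,nmol/site,22.49
SB366791_ipl,2.00,nmol/site,52.85
SB366791_ipl,2.00,nmol/site,-10.13
SB366791_ipl,6.00,nmol/site,30.62
SB366791_ipl,6.00,nmol/site,65.31
SB366791_ipl,6.00,nmol/site,17.07
SB366791_ipl,6.00,nmol/site,84.28
SB366791_ipl,6.00,nmol/site,25.95
SB366791_ipl,6.00,nmol/site,23.42
SB366791_ipl,6.00,nmol/site,18.99
SB366791_ipl,6.00,nmol/site,6.33
SB366791_ipl,6.00,nmol/site,60.13
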