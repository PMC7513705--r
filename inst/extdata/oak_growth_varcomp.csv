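trait,term,variance,se
height,site,4999.1,5067.3
height,provenance,2067.1,1103.9
height,family,896.73,132.29
height,block,58.52,62.95
height,prov_x_site,623.45,227.3
height,fam_x_site,283.55,87.97
height,residual,13743,208.78
dbh,site,0.7257,0.73647
dbh,provenance,0.13028,0.08454
dbh,family,0.24505,0.035
dbh,block,0.009874,0.01093
dbh,prov_x_site,0.093256,0.03596
dbh,fam_x_site,0.079982,0.02186
dbh,residual,3.2761,0.04977
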