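provenance_id,cluster,name,region,lat,lon,MAT,MAP,MWMT,MCMT
1,2,Geinberg,Austria-north,48.28,13.31,8.69,890.66,19.05,-2.64
2,2,Linz,Austria-north,48.33,14.29,8.90,815.02,19.50,-2.78
8,2,Rainfeld,Austria-north,48.04,15.73,8.79,762.58,19.27,-2.55
6,1,Braunsberger Wald,Austria-northeast,48.47,16.33,9.36,627.99,20.17,-2.69
12,1,Luising,Austria-southeast,47.02,16.48,9.58,614.18,20.49,-2.46
14,4,Klagenfurt,Austria-south,46.63,14.35,8.35,1009.52,19.46,-4.24
17,5,Hluboka (CZ),Czech Republic,49.09,14.44,7.36,497.90,17.92,-4.10
18,3,Kutina (HR),Croatia-west,45.43,16.68,10.85,837.72,21.64,-1.42
21,3,Velika Gorica (HR),Croatia-west,45.67,16.16,10.69,920.34,21.54,-1.59
19,3,Murska suma (SLO),Slovenia-north,46.50,16.51,9.83,802.68,20.74,-2.41
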