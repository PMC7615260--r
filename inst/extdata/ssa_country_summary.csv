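level,region,name,n,percentage,anemia_prevalence,temp_mean,temp_sd,temp_min,temp_max
region,Eastern Africa,Eastern Africa,103628,37.63,55.36,21.7,2.6,12.6,32.6
country,Eastern Africa,Burundi,16974,6.16,53.31,21.0,1.4,17.7,26.1
country,Eastern Africa,Ethiopia,19529,7.09,55.01,21.3,4.2,12.6,32.6
country,Eastern Africa,Malawi,10992,3.99,65.59,22.2,1.7,16.9,26.6
country,Eastern Africa,Mozambique,4355,1.58,66.25,23.6,1.5,18.4,26.7
country,Eastern Africa,Rwanda,10636,3.86,42.51,19.5,1.7,15.6,25.7
country,Eastern Africa,Tanzania,14766,5.36,56.39,23.4,2.4,15.4,27.1
country,Eastern Africa,Uganda,7842,2.85,58.70,23.0,1.8,15.1,27.1
country,Eastern Africa,Zambia,7722,2.80,58.43,21.9,1.3,19.0,26.1
country,Eastern Africa,Zimbabwe,10812,3.93,51.06,21.3,1.8,17.4,27.0
region,Central Africa,Central Africa,58407,21.21,63.94,24.1,2.3,16.2,29.8
country,Central Africa,Angola,11198,4.07,64.99,22.8,1.9,18.6,25.9
country,Central Africa,Cameroon,23502,8.53,62.24,24.7,2.6,18.7,29.8
country,Central Africa,Congo Democratic Republic,20692,7.51,65.32,24.1,2.1,16.2,27.3
country,Central Africa,Gabon,3015,1.09,63.81,25.0,0.7,22.6,26.1
region,Western Africa,Western Africa,103586,37.62,73.42,27.7,1.4,19.8,31.8
country,Western Africa,Benin,17652,6.41,67.14,27.4,0.8,25.5,30.1
country,Western Africa,Burkina Faso,17532,6.37,89.25,28.8,0.6,26.8,30.7
country,Western Africa,Cote d'Ivoire,5560,2.02,75.29,26.3,0.6,24.2,28.0
country,Western Africa,Gambia,3256,1.18,53.38,27.7,1.7,25.1,30.3
country,Western Africa,Ghana,7549,2.74,74.84,27.0,1.1,25.1,29.5
country,Western Africa,Liberia,2149,0.78,71.20,25.9,0.4,24.6,26.6
country,Western Africa,Nigeria,10168,3.69,68.79,27.0,1.2,19.8,29.8
country,Western Africa,Senegal,36840,13.38,71.68,28.0,1.7,23.7,31.8
country,Western Africa,Togo,2880,1.05,71.01,27.2,1.0,24.8,29.4
region,Southern Africa,Southern Africa,9756,3.54,49.36,17.0,4.6,12.8,25.9
country,Southern Africa,Eswatini,3546,1.29,43.99,19.1,2.1,15.4,25.8
country,Southern Africa,Lesotho,3876,1.41,51.24,16.3,2.8,12.8,25.7
country,Southern Africa,Namibia,1529,0.56,51.21,22.4,2.0,15.9,25.9
country,Southern Africa,South Africa,805,0.29,60.50,19.4,2.0,13.8,24.1
total,Total,Total,275377,100.00,63.76,24.4,3.7,12.6,32.6
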