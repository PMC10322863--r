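year,period,nep,gpp,reco,h,le,rn,ppfd,ta,prec,vpd,gs_length
2015,full,309,1675,1366,14.6,43.3,78.4,237.5,10.3,550,4.0,NA
2016,full,354,1724,1370,14.9,44.0,78.0,222.1,9.9,389,4.2,NA
2017,full,439,1629,1190,9.6,46.3,60.9,201.1,9.8,610,3.8,NA
2018,full,424,1572,1147,21.1,42.2,67.9,272.3,10.9,302,5.9,NA
2019,full,274,1291,1016,17.0,41.9,70.4,250.5,11.1,471,5.3,NA
2020,full,372,1694,1322,16.1,44.8,63.8,255.7,11.3,478,5.2,NA
2015,growing_season,544,1607,1064,23.7,65.4,120.6,332.8,14.4,353,5.6,205
2016,growing_season,578,1614,1036,28.1,66.5,121.9,313.8,14.7,261,6.1,207
2017,growing_season,622,1552,930,18.9,69.2,95.7,280.2,14.2,438,5.1,215
2018,growing_season,585,1528,944,33.4,59.1,99.8,368.8,16.1,130,8.5,227
2019,growing_season,498,1253,756,30.2,57.8,101.5,339.1,14.9,322,7.0,230
2020,growing_season,614,1628,1014,29.7,65.8,101.2,360.3,15.5,315,7.2,211
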