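"equation_id","sex","age","weight","height","fat_free_mass","fat_mass","expected_kcal_d","arithmetic"
"who","male",8,30,NA,NA,NA,1176,"22.7*30+495"
"who","female",14,50,NA,NA,NA,1371,"12.5*50+746"
"who","male",12,60,NA,NA,NA,1755,"18.4*60+651"
"schofield","male",8,30,130,NA,NA,1171.63,"19.589*30+1.302*130+414.7"
"schofield","female",12,45,150,NA,NA,1274.345,"8.361*45+4.654*150+200.0"
"schofield","male",15,60,170,NA,NA,1723.07,"16.245*60+1.371*170+515.3"
"iom","male",10,35,140,NA,NA,1303.8,"68-43.3*10+7.12*140+19.2*35"
"iom","female",12,45,150,NA,NA,1270.8,"189-17.6*12+6.25*150+7.9*45"
"iom","male",16,65,175,NA,NA,1869.2,"68-43.3*16+7.12*175+19.2*65"
"kim","male",8,30,NA,NA,NA,1043.58,"632.4+15.66*8+9.53*30"
"kim","female",5,20,NA,NA,NA,901.3,"632.4+15.66*5+9.53*20"
"kim","female",11,40,NA,NA,NA,1185.86,"632.4+15.66*11+9.53*40"
"henry","male",8,30,130,NA,NA,855.46,"15.1*30+0.742*130+306"
"henry","female",9,28,128,NA,NA,1063,"15.9*28+2.1*128+349"
"henry","female",15,52,160,NA,NA,1349.2,"9.40*52+2.49*160+462"
"molnar","male",12,50,150,NA,NA,1388.695,"(50.2*50+29.6*150-144.5*12-550*0+594.3)/4.184"
"molnar","female",12,50,150,NA,NA,1257.2419,"(50.2*50+29.6*150-144.5*12-550*1+594.3)/4.184"
"molnar","male",15,60,170,NA,NA,1546.5583,"(50.2*60+29.6*170-144.5*15-550*0+594.3)/4.184"
"muller_a","male",10,40,145,NA,NA,1286.9383,"(0.02606*40+0.04129*145+0.311*0-0.08369*10-0.808)*1000/4.184"
"muller_a","female",13,48,155,NA,NA,1449.7753,"(0.02606*48+0.04129*155+0.311*1-0.08369*13-0.808)*1000/4.184"
"muller_a","male",16,62,172,NA,NA,1570.4015,"(0.02606*62+0.04129*172+0.311*0-0.08369*16-0.808)*1000/4.184"
"muller_b","female",12,NA,NA,35,12,1442.7796,"(0.07885*35+0.02132*12+0.327*1+2.694)*1000/4.184"
"muller_b","male",12,NA,NA,42,10,1486.3528,"(0.07885*42+0.02132*10+0.327*0+2.694)*1000/4.184"
"muller_b","male",9,NA,NA,25,8,1155.7863,"(0.07885*25+0.02132*8+0.327*0+2.694)*1000/4.184"
"derumeaux_burel","male",10,NA,NA,30,NA,1394.2878,"(0.1371*30-0.1644*10+3.3647)*1000/4.184"
"derumeaux_burel","female",14,NA,NA,38,NA,1499.2591,"(0.1371*38-0.1644*14+3.3647)*1000/4.184"
"derumeaux_burel","female",6,NA,NA,18,NA,1158.2457,"(0.1371*18-0.1644*6+3.3647)*1000/4.184"
"schmelzle","male",10,40,145,NA,NA,1369.5,"6.6*40+13.1*145-794"
"schmelzle","female",10,50,150,NA,NA,1300,"11.9*50+0.84*150+579"
"schmelzle","female",14,55,160,NA,NA,1367.9,"11.9*55+0.84*160+579"
"tverskaya","male",12,NA,NA,40,15,1598.5,"775+28.4*40-37*12+3.3*15+82*1"
"tverskaya","female",12,NA,NA,40,15,1516.5,"775+28.4*40-37*12+3.3*15+82*0"
"tverskaya","female",8,NA,NA,22,9,1133.5,"775+28.4*22-37*8+3.3*9+82*0"
"lazzer_a","male",12,50,155,NA,NA,1558.1206,"(1*892.68-12*115.93+50*54.96+1.55*1816.23+1454.50)/4.184; HT 155 cm = 1.55 m"
"lazzer_a","female",14,60,160,NA,NA,1442.4111,"(0*892.68-14*115.93+60*54.96+1.60*1816.23+1454.50)/4.184"
"lazzer_a","male",17,80,175,NA,NA,1900.4714,"(1*892.68-17*115.93+80*54.96+1.75*1816.23+1454.50)/4.184"
"lazzer_b","female",14,NA,NA,38,18,1366.8141,"(0*909.12-14*107.48+38*68.39+18*55.19+3631.23)/4.184"
"lazzer_b","male",14,NA,NA,48,14,1694.7921,"(1*909.12-14*107.48+48*68.39+14*55.19+3631.23)/4.184"
"lazzer_b","male",8,NA,NA,24,7,1364.2925,"(1*909.12-8*107.48+24*68.39+7*55.19+3631.23)/4.184"
"new_ffm","female",12,NA,NA,41.6,NA,1519.7448,"505.412+24.383*41.6"
"new_ffm","male",12,NA,NA,30,NA,1236.902,"505.412+24.383*30"
"new_ffm","male",10,NA,NA,0.001,NA,505.4364,"505.412+24.383*0.001"
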