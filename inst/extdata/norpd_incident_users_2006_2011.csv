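sex,year,person_years,outcome,count,rate,ci_low,ci_high
female,2006,2347036,any,7531,320,314,328
female,2007,2366461,any,7769,328,321,336
female,2008,2390716,any,7677,321,314,328
female,2009,2418595,any,7832,323,317,331
female,2010,2445249,any,7778,318,311,325
female,2011,2473228,any,7269,293,287,301
female,2006,2347036,oad,6752,288,281,295
female,2007,2366461,oad,6927,293,286,300
female,2008,2390716,oad,6717,281,274,288
female,2009,2418595,oad,6912,286,279,293
female,2010,2445249,oad,6817,279,272,286
female,2011,2473228,oad,6369,258,251,264
female,2006,2347036,insulin_only,670,29,26,31
female,2007,2366461,insulin_only,679,29,27,31
female,2008,2390716,insulin_only,783,33,31,35
female,2009,2418595,insulin_only,745,31,29,33
female,2010,2445249,insulin_only,784,32,30,34
female,2011,2473228,insulin_only,NA,NA,NA,NA
male,2006,2314006,any,7829,338,331,346
male,2007,2342823,any,8374,357,350,365
male,2008,2377361,any,8655,364,356,372
male,2009,2411205,any,8620,357,350,365
male,2010,2443697,any,8605,352,345,360
male,2011,2479989,any,8246,332,325,340
male,2006,2314006,oad,6830,295,288,302
male,2007,2342823,oad,7326,313,306,320
male,2008,2377361,oad,7498,315,308,323
male,2009,2411205,oad,7453,309,302,316
male,2010,2443697,oad,7475,306,299,313
male,2011,2479989,oad,7131,288,281,294
male,2006,2314006,insulin_only,756,33,30,35
male,2007,2342823,insulin_only,793,34,32,36
male,2008,2377361,insulin_only,845,36,33,38
male,2009,2411205,insulin_only,839,35,33,37
male,2010,2443697,insulin_only,813,33,31,36
male,2011,2479989,insulin_only,NA,NA,NA,NA
total,2006,4661041,any,15360,329,324,334
total,2007,4709284,any,16143,342,338,348
total,2008,4768077,any,16332,342,337,348
total,2009,4829800,any,16452,340,335,346
total,2010,4888946,any,16383,335,330,340
total,2011,4953217,any,15515,313,308,318
total,2006,4661041,oad,13582,291,287,297
total,2007,4709284,oad,14253,303,298,308
total,2008,4768077,oad,14215,298,293,303
total,2009,4829800,oad,14365,297,293,302
total,2010,4888946,oad,14292,292,288,297
total,2011,4953217,oad,13500,273,268,277
total,2006,4661041,insulin_only,1426,31,29,32
total,2007,4709284,insulin_only,1472,31,30,33
total,2008,4768077,insulin_only,1628,34,33,36
total,2009,4829800,insulin_only,1584,33,31,34
total,2010,4888946,insulin_only,1597,33,31,34
total,2011,4953217,insulin_only,NA,NA,NA,NA
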