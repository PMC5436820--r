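# Published display-rounded monthly estimates for the 2015 Sainte Luce
# lobster season. Columns follow the raising identities E = D.B.F,
# L = E.C, V = L.P; B and C are rounded to 2 dp and F, E, L, V to
# integers, so the printed rows need not satisfy the identities exactly.
# January was not surveyed; its landings are the mean of February and
# March (imputed = true).
month,D,n,B,F,E,C,L,P,V,imputed
2015-01,31,NA,NA,NA,NA,NA,1015,15000,15230654,true
2015-02,28,11,0.74,70,1348,0.86,1255,15000,18830197,false
2015-03,31,13,0.47,68,930,0.77,775,15000,11631111,false
2015-04,30,12,0.67,73,1373,1.07,1580,15000,23696567,false
2015-05,31,17,0.19,91,495,1.02,536,15000,8039411,false
2015-06,30,15,0.09,94,245,0.58,149,15000,2240704,false
2015-07,31,19,0.80,82,1926,2.24,4593,20000,91865265,false
2015-08,31,17,0.80,79,1827,0.78,1531,20000,30629189,false
2015-09,30,16,0.50,70,965,0.53,554,20000,11081059,false
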