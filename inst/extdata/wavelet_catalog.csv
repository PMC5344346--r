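wavelet,family,filter_length,vanishing_moments
bior1.1,bior,2,1
bior1.3,bior,6,1
bior1.5,bior,10,1
bior2.2,bior,6,2
bior2.4,bior,10,2
bior2.6,bior,14,2
bior2.8,bior,18,2
bior3.1,bior,4,3
bior3.3,bior,8,3
bior3.5,bior,12,3
bior3.7,bior,16,3
bior3.9,bior,20,3
bior4.4,bior,10,4
bior5.5,bior,12,5
bior6.8,bior,18,6
coif1,coif,6,2
coif2,coif,12,4
coif3,coif,18,6
coif4,coif,24,8
coif5,coif,30,10
db1,db,2,1
db2,db,4,2
db3,db,6,3
db4,db,8,4
db5,db,10,5
db6,db,12,6
db7,db,14,7
db8,db,16,8
db9,db,18,9
db10,db,20,10
rbio1.1,rbio,2,1
rbio1.3,rbio,6,1
rbio1.5,rbio,10,1
rbio2.2,rbio,6,2
rbio2.4,rbio,10,2
rbio2.6,rbio,14,2
rbio2.8,rbio,18,2
rbio3.1,rbio,4,3
rbio3.3,rbio,8,3
rbio3.5,rbio,12,3
rbio3.7,rbio,16,3
rbio3.9,rbio,20,3
rbio4.4,rbio,10,4
rbio5.5,rbio,12,5
rbio6.8,rbio,18,6
sym2,sym,4,2
sym3,sym,6,3
sym4,sym,8,4
sym5,sym,10,5
sym6,sym,12,6
sym7,sym,14,7
sym8,sym,16,8
dmey,dmey,102,NA
haar,haar,2,1
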