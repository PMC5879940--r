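patient_id,method,observer,session,name,value_or_x,y
1,lewinnek,1,1,D1,25,
1,lewinnek,1,1,D2,50,
1,widmer,1,1,S,16.6,
1,widmer,1,1,TL,33.3,
1,liaw,1,1,A,-25,0
1,liaw,1,1,B,25,0
1,liaw,1,1,E,0,12.5
2,hassan,1,1,D,50,
2,hassan,1,1,m,39,
2,hassan,1,1,h,10.37,
2,ackland,1,1,a,25,
2,ackland,1,1,x,25,
2,ackland,1,1,y,12.5,
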