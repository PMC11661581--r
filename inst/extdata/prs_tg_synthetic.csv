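rsid,effect_allele,effect_allele_freq,beta
rs9278271,T,0.4633,-0.13452
rs9247570,T,0.8589,0.03504
rs9244740,G,0.3112,0.06312
rs9242666,A,0.4428,0.03194
rs9265536,G,0.0545,0.02849
rs9285604,C,0.485,-0.08349
rs9279489,T,0.9379,-0.06975
rs9279986,A,0.9259,-0.058
rs9233302,G,0.7747,-0.11548
rs9253576,G,0.4177,0.14103
rs9286322,G,0.5295,-0.03657
rs9230579,A,0.4598,0.15605
rs9259787,G,0.1952,-0.12649
rs9293521,T,0.1025,0.03007
rs9264357,A,0.2976,-0.11485
rs9235640,G,0.2518,0.03528
rs9216339,C,0.1894,-0.09399
rs9252392,T,0.2067,-0.00965
rs9245735,G,0.1676,0.04836
rs9277259,T,0.0564,0.11019
rs9237137,A,0.3332,-0.03454
rs9224349,G,0.463,0.05166
rs9287347,C,0.7746,0.04123
rs9293555,C,0.9487,0.06799
rs9244884,C,0.874,0.16933
rs9221874,G,0.1024,-0.03747
rs9280268,A,0.1816,0.05861
rs9241583,C,0.3825,-0.03029
rs9282505,G,0.5809,-0.08607
rs9284403,T,0.2645,0.03146
rs9237698,T,0.4442,-0.02942
rs9247184,T,0.1142,-0.08848
rs9217820,C,0.6799,-0.08083
rs9229115,A,0.1951,-0.04178
rs9281728,C,0.1763,0.04153
rs9242234,A,0.5716,0.02394
rs9250779,T,0.8694,0.10067
rs9249061,C,0.5906,-0.09644
rs9271480,G,0.1483,0.05205
rs9236791,G,0.6856,-0.02144
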