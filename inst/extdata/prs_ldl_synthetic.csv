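rsid,effect_allele,effect_allele_freq,beta
rs9118999,T,0.4804,0.12882
rs9121844,G,0.4447,-0.04598
rs9194526,T,0.3991,-0.04269
rs9186221,A,0.4216,0.02726
rs9195332,A,0.7743,-0.12538
rs9124275,A,0.124,-0.03573
rs9152308,T,0.7778,0.03258
rs9115173,G,0.7607,-0.13382
rs9140383,G,0.9241,-0.04645
rs9142473,T,0.8035,-0.10543
rs9155654,C,0.3582,-0.04127
rs9192554,G,0.7467,0.09854
rs9167169,T,0.0784,-0.06543
rs9145864,T,0.5037,-0.05343
rs9122128,A,0.7708,-0.04552
rs9170710,T,0.7988,0.06315
rs9165357,G,0.3973,0.03779
rs9126480,T,0.9272,-0.10092
rs9159525,T,0.2058,-0.14982
rs9156318,C,0.3055,-0.0411
rs9148293,A,0.5241,0.1047
rs9167008,A,0.2455,0.06603
rs9156644,A,0.5449,-0.17002
rs9172737,C,0.3098,-0.07298
rs9154380,C,0.6028,0.07344
rs9151151,T,0.6788,0.07703
rs9185415,A,0.3254,-0.43186
rs9110243,G,0.9309,-0.06075
rs9114599,A,0.6639,0.07227
rs9165522,G,0.5673,-0.07057
rs9115594,G,0.6237,-0.05985
rs9111208,T,0.4019,-0.03825
rs9146564,C,0.6037,0.04983
rs9195418,G,0.4512,0.1741
rs9174795,C,0.463,0.14004
rs9178685,C,0.6521,-0.06394
rs9183240,T,0.4914,-0.05709
rs9131085,T,0.224,-0.07214
rs9168033,C,0.7103,0.04683
rs9130852,T,0.6748,-0.05349
rs9116133,A,0.3925,-0.08807
rs9186588,C,0.7661,0.24479
rs9166499,A,0.8317,-0.17194
rs9145607,G,0.7003,-0.10402
rs9148915,A,0.9147,-0.08793
rs9137071,G,0.8803,0.12385
rs9141510,T,0.7178,0.05447
rs9113246,A,0.5877,-0.06335
rs9142339,T,0.1357,0.10052
rs9114801,G,0.7098,-0.08154
rs9161080,C,0.1323,-0.22081
rs9160911,T,0.308,-0.04206
rs9199447,A,0.8997,-0.08706
rs9139753,G,0.3253,0.13244
rs9172393,C,0.1831,-0.09421
rs9195652,T,0.39,0.03163
rs9129622,A,0.3731,-0.13702
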