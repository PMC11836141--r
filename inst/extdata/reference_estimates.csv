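experiment,session,condition,n,s,r1,g,r2,fa_observed
1,1,rest,51,0.91,0.98,0.46,0.73,0.05
1,1,social,50,0.92,0.98,0.38,0.73,0.04
1,1,vocab,53,0.87,0.96,0.27,0.68,0.04
2,1,rest,53,0.92,1.00,0.41,0.63,0.03
2,1,social,52,0.92,1.00,0.27,0.66,0.02
2,1,vocab,52,0.89,0.99,0.27,0.63,0.03
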