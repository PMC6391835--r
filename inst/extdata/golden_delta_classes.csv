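source,pre_delta,n_c1_acid,n_c4_keto,n_c6_aldehyde,n_c6_acid,n_lactone,post_lactones,printed_delta,confidence,note
spectrum classes,0,0,0,0,0,0,0,0,high,non-oxidized
spectrum classes,-2,0,1,0,0,0,0,-2,high,C4 ketoaldose
spectrum classes,-2,0,0,1,0,0,0,-2,high,C6 hexodialdose
spectrum classes,16,1,0,0,0,0,0,16,high,C1 aldonic acid
spectrum classes,14,1,1,0,0,0,0,14,high,C1-/C4-oxidized
spectrum classes,14,0,0,0,1,0,0,14,high,C6 glucuronosyl
spectrum classes,12,1,0,0,1,1,0,12,high,C1-/C6-oxidized lactone
spectrum classes,12,0,1,0,1,0,0,12,high,C4-/C6-oxidized
spectrum classes,28,1,1,0,1,0,0,28,high,C1-/C6-/C4-oxidized
spectrum classes,28,0,0,0,2,0,0,28,high,C6-/C6-oxidized
post-Br2 classes,0,0,0,0,0,0,0,16,high,unmodified chain -> C1 acid
post-Br2 classes,-2,0,1,0,0,0,0,14,high,C4 ketone inert; reducing end oxidized
post-Br2 classes,-2,0,0,1,0,0,0,30,high,C6 aldehyde + reducing end oxidized
post-Br2 classes,-4,0,1,1,0,0,0,28,high,C6-/C4-oxidized + reducing end
post-Br2 classes,-4,0,0,2,0,0,0,44,high,two C6 aldehydes + reducing end
post-Br2 classes,-4,0,0,2,0,0,1,26,low,printed as C1-/C6-/C6; modeled here as the mono-lactone of the +44 class
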