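zone,loss_ha,loss_pct,gain_ha,gain_pct
"1,000–1,499",-261265,-1.0,195679,0.7
"1,500–1,999",-99630,-0.6,276485,1.6
"2,000–2,499",-51020,-0.4,236612,1.7
"2,500–2,999",-26964,-0.2,151834,1.3
"3,000–3,499",-27158,-0.3,74041,0.7
"3,500–3,999",-21697,-0.2,15512,0.1
">4,000",-619,0.0,38627,0.3
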