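structure_id,enzyme_form,space_group,molar_ratio,chain,conformation,partner,occupancy
WT-6(P/S)-2FA,WT,P212121,0.14,A,closed,D,0.7
WT-6(P/S)-2FA,WT,P212121,0.14,B,open,E,NA
WT-6(P/S)-2FA,WT,P212121,0.14,C,open,F,NA
WT-6(P/S)-2FA,WT,P212121,0.14,D,open,A,NA
WT-6(P/S)-2FA,WT,P212121,0.14,E,open,B,NA
WT-6(P/S)-2FA,WT,P212121,0.14,F,closed,C,0.7
WT-6(P/S)-6FA,WT,P6122,0.57,A,closed,D,0.8
WT-6(P/S)-6FA,WT,P6122,0.57,D,open,A,0.5
WT-6(P/S)-6FA,WT,P6122,0.57,B,open,B',0.4
WT-6(P/S)-6FA,WT,P6122,0.57,A',closed,D',0.8
WT-6(P/S)-6FA,WT,P6122,0.57,D',open,A',0.5
WT-6(P/S)-6FA,WT,P6122,0.57,B',open,B,0.4
DM-6(P/S)-2FA,DM,P212121,0.4,A,closed,D,NA
DM-6(P/S)-2FA,DM,P212121,0.4,B,open,E,NA
DM-6(P/S)-2FA,DM,P212121,0.4,C,open,F,0.7
DM-6(P/S)-2FA,DM,P212121,0.4,D,open,A,0.7
DM-6(P/S)-2FA,DM,P212121,0.4,E,open,B,NA
DM-6(P/S)-2FA,DM,P212121,0.4,F,closed,C,NA
DM-6(P/S)-4FA,DM,P212121,0.6,A,closed,D,0.6
DM-6(P/S)-4FA,DM,P212121,0.6,B,open,E,NA
DM-6(P/S)-4FA,DM,P212121,0.6,C,open,F,0.6
DM-6(P/S)-4FA,DM,P212121,0.6,D,open,A,0.6
DM-6(P/S)-4FA,DM,P212121,0.6,E,open,B,NA
DM-6(P/S)-4FA,DM,P212121,0.6,F,closed,C,0.6
DM-6(P/S)-6FA,DM,P6122,1.2,A,closed,D,0.7
DM-6(P/S)-6FA,DM,P6122,1.2,D,open,A,0.5
DM-6(P/S)-6FA,DM,P6122,1.2,B,open,B',0.6
DM-6(P/S)-6FA,DM,P6122,1.2,A',closed,D',0.7
DM-6(P/S)-6FA,DM,P6122,1.2,D',open,A',0.5
DM-6(P/S)-6FA,DM,P6122,1.2,B',open,B,0.6
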