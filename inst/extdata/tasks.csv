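task,kind,class,member_codes
form,form,N,N;LBBB;RBBB;AESC;NESC
form,form,SVEB,PAC;PAC_ABERR;NPC;SVPB
form,form,VEB,PVC;VESC
rhythm,rhythm,SINUS,SINUS
rhythm,rhythm,STACH,STACH
rhythm,rhythm,SBRAD,SBRAD
rhythm,rhythm,SVTA,SVTA
rhythm,rhythm,AFIB,AFIB
rhythm,rhythm,AFL,AFL
rhythm_reduced,rhythm,AFIB,AFIB
rhythm_reduced,rhythm,SINUS,SINUS
rhythm_reduced,rhythm,OTHER,
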