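dataset,raw_symbol,unified_code,kind
mitbih_ar,N,N,beat
mitbih_ar,L,LBBB,beat
mitbih_ar,R,RBBB,beat
mitbih_ar,e,AESC,beat
mitbih_ar,j,NESC,beat
mitbih_ar,A,PAC,beat
mitbih_ar,a,PAC_ABERR,beat
mitbih_ar,J,NPC,beat
mitbih_ar,S,SVPB,beat
mitbih_ar,V,PVC,beat
mitbih_ar,E,VESC,beat
mitbih_ar,F,FUSION,beat
mitbih_ar,/,PACE,beat
mitbih_ar,f,PFUS,beat
mitbih_ar,Q,UNKNOWN,beat
mitbih_ar,N,SINUS,rhythm
mitbih_ar,AFIB,AFIB,rhythm
mitbih_ar,AFL,AFL,rhythm
mitbih_ar,SVTA,SVTA,rhythm
mitbih_ar,SBR,SBRAD,rhythm
mitbih_ar,VT,VT,rhythm
mitbih_ar,B,BIGEMINY,rhythm
mitbih_ar,T,TRIGEMINY,rhythm
mitbih_ar,IVR,IVR,rhythm
mitbih_ar,NOISE,NOISE,rhythm
arr10000,SR,SINUS,rhythm
arr10000,AF,AFIB,rhythm
arr10000,AFIB,AFIB,rhythm
arr10000,AFL,AFL,rhythm
arr10000,ST,STACH,rhythm
arr10000,SB,SBRAD,rhythm
arr10000,SVT,SVTA,rhythm
synth,N,N,beat
synth,V,PVC,beat
synth,A,PAC,beat
synth,N,SINUS,rhythm
synth,AFIB,AFIB,rhythm
synth,AFL,AFL,rhythm
synth,ST,STACH,rhythm
synth,SBR,SBRAD,rhythm
synth,SVTA,SVTA,rhythm
synthrec,SINUS,SINUS,rhythm
synthrec,AFIB,AFIB,rhythm
synthrec,AFL,AFL,rhythm
synthrec,STACH,STACH,rhythm
synthrec,SBRAD,SBRAD,rhythm
synthrec,SVTA,SVTA,rhythm
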