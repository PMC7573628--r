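(Atr:173,(Pah:160,((Osj:50,Zma:50):100,((((Lpu:19,Vsu:19):49,Fal:68):40,((Ath:95,Mob:95):5,Sbi:100):8):9,Vvi:117):33):10):13):0;
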