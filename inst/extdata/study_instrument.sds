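($HUM = R EO)
($DIS = ED PD)
($NOI = MO S1 S2 S3)
($TO = TO)
($EX = EE)
($WHI = S5)
($ORD = DO)
($DIN = QA QACL FF FO RP PV RT)
($MNT = MNT)
($CFR = CFR)
($EXP = RA EC CD RB)
($DEF = RD_N_P CT)
($Q = Q)
($TURN = O G D JM F L M);
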