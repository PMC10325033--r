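>BDNF_precursor_synthetic synthetic stand-in; BDNF entry: true length and true mature region (131-249), pre/pro region synthetic
MTILFLTMVISYFGCMKADNFSMKGAFTAEIPEVHIYFSRNICWLLPCNLQNDGAIWDVM
INKGCERKCPFDKILTNVKFPLPWIHNYGGDMQLYQFSCWSEKKRFPVNIYTQHPSCGFK
KGSMWFWLDAHSDPARRGELSVCDSISEWVTAADKKTAVDMSGGTVTVLEKVPVSKGQLK
QYFYETKCNPMGYTKEGCRGIDKRHWNSQCRTTQSYVRALTMDSKKRIGWRFIRIDTSCV
CTLTIKRGR
>NGF_precursor_synthetic synthetic stand-in; BDNF entry: true length and true mature region (131-249), pre/pro region synthetic
MAPPFCGPPYKFNCICNYWTIKHDVGDAFWFAQWYEAVSFNFAFFRVRDSVRWLDDAMSI
LRSNIRAYEMKMMGSHARCAYQRREMLCHMNYPQCGCETDQWNYHMQHIDLHAMLMTEFT
VTSARKRCVGNCDHGASKVECHSTMSWGERMTYKESTQHSLHAYACCYSYGLMFRFVPMS
FRERYTVFRILDCWDWKLKQKEIRPVTEGKIRKADSEHLMNYTHCHPICSSAIWRMGTPY
F
>NT3_precursor_synthetic synthetic stand-in; BDNF entry: true length and true mature region (131-249), pre/pro region synthetic
MYMVHMRFMLHENHQCWEVDDRRTCSMTEKYKFIQWGYRSSVNMLIQGHRMMITWGGMSW
IFSDEDIVMMDFPYWLEDMAKLDHLQCAANVNGAKRLGHWHEWIQVQMVHEQAPAYWSHK
FYKDWWICLLVNSLLMTYFITGLLCICPPGVFVGSATEMMECDNWCQKRQRLDEEFSCGT
TINAEVVLFSHTFDNESTIGPFRPIQDKLTMQNYGAHAAQDTHASGRFYKKRFWVFSNVD
FNMQGMQANGISARLRDN
>NT4_precursor_synthetic synthetic stand-in; BDNF entry: true length and true mature region (131-249), pre/pro region synthetic
MNIPHIGFVGPCEVVYYWQLVVSGDWEKEDPDRIGGFGDMAYATYICCYPLYAVLVNIKH
WHWFWSLAGNAAYVSDEVLHPPWARAWARGGEEPMRYGMIPRRYTCMMFSQMEMAPNTRE
QCHGQQDPQMDHRDVRTNYLIAPHAQENTAPNVHPMAIQIWMTKMGWKIQCRIYAACFMT
FAYSMVYTQEADVFEMRPDNLTATVPHYW
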