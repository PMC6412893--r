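dataset,category,abbrev,n_samples,printed_pct
HMM,Stilling,STI,1325,12.42
HMM,Walking,WAL,2216,20.78
HMM,Elevator_up,ELU,685,6.42
HMM,Elevator_down,ELD,730,6.84
HMM,Escalator_up,ESU,2216,20.78
HMM,Escalator_down,ESD,1598,14.98
HMM,Walking_up,WAU,864,8.10
HMM,Walking_down,WAD,1029,9.65
HSBD,Walking,WAL,1772,17.12
HSBD,Walking_up,WAU,1544,14.91
HSBD,Walking_down,WAD,1406,13.58
HSBD,Standing,STA,1777,17.17
HSBD,Sitting,SIT,1906,18.41
HSBD,Laying,LAY,1944,18.78
HDBD,Stand-to-sit,S2SI,697,12.48
HDBD,Sit-to-stand,SI2S,192,3.43
HDBD,Sit-to-lie,SI2L,1193,21.36
HDBD,Lie-to-sit,L2SI,879,15.74
HDBD,Stand-to-lie,S2L,1753,31.39
HDBD,Lie-to-stand,L2S,870,15.58
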