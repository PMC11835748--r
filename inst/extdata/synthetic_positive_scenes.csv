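"onset_s","duration_s","valence","description"
36.8,24.4,"positive","synthetic positive scene 01"
63.2,24.5,"positive","synthetic positive scene 02"
89.7,23.1,"positive","synthetic positive scene 03"
153.7,21.9,"positive","synthetic positive scene 04"
177.6,22.5,"positive","synthetic positive scene 05"
202.1,19.6,"positive","synthetic positive scene 06"
223.7,14,"positive","synthetic positive scene 07"
239.7,16.2,"positive","synthetic positive scene 08"
257.9,34.4,"positive","synthetic positive scene 09"
294.3,19.5,"positive","synthetic positive scene 10"
331.8,33.6,"positive","synthetic positive scene 11"
425.7,12,"positive","synthetic positive scene 12"
605.4,15.4,"positive","synthetic positive scene 13"
649.6,20.4,"positive","synthetic positive scene 14"
820.9,24.6,"positive","synthetic positive scene 15"
943.8,23.7,"positive","synthetic positive scene 16"
969.5,33.2,"positive","synthetic positive scene 17"
1004.7,24.6,"positive","synthetic positive scene 18"
1031.3,9,"positive","synthetic positive scene 19"
1042.3,20.2,"positive","synthetic positive scene 20"
1091.1,9.1,"positive","synthetic positive scene 21"
1103.1,10.6,"positive","synthetic positive scene 22"
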