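gene	condition	replicate	ct
miR5293	0h	1	25.88
5.8S rRNA	0h	1	16.93
miR5293	0h	2	25.98
5.8S rRNA	0h	2	16.98
miR5293	0h	3	26.07
5.8S rRNA	0h	3	16.91
miR5293	6h	1	22.78
5.8S rRNA	6h	1	17
miR5293	6h	2	22.56
5.8S rRNA	6h	2	16.97
miR5293	6h	3	22.79
5.8S rRNA	6h	3	16.96
miR5293	12h	1	23.81
5.8S rRNA	12h	1	16.98
miR5293	12h	2	24.08
5.8S rRNA	12h	2	16.93
miR5293	12h	3	23.79
5.8S rRNA	12h	3	16.79
miR5293	24h	1	25.03
5.8S rRNA	24h	1	16.94
miR5293	24h	2	25.16
5.8S rRNA	24h	2	17.01
miR5293	24h	3	24.86
5.8S rRNA	24h	3	17.07
miR5293	48h	1	25.5
5.8S rRNA	48h	1	17.21
miR5293	48h	2	25.63
5.8S rRNA	48h	2	16.94
miR5293	48h	3	25.66
5.8S rRNA	48h	3	17.03
miR5293	96h	1	25.96
5.8S rRNA	96h	1	16.97
miR5293	96h	2	26.26
5.8S rRNA	96h	2	17.01
miR5293	96h	3	26.1
5.8S rRNA	96h	3	16.92
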