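muscle	cluster	sensory	sympathetic	motor
Extensor carpi radialis	C1	4.57	7.33	22.58
Extensor carpi ulnaris	C1	10.54	14.98	26.77
Extensor digitorum longus	C1	1.28	11.26	20.98
Flexor carpi radialis	C1	10.12	12.94	21.19
Flexor carpi ulnaris	C2	7.41	1.16	10.24
Palmaris longus	C2	3.63	1.42	17.44
Plantaris	C2	7.65	1.58	10.23
Soleus	C2	5.51	6.67	10.88
Biceps femoris	C3	0.10	0.23	2.34
Flexor digitorum profundus (lower)	C3	1.43	0.61	4.70
Flexor digitorum profundus (upper)	C3	3.68	1.61	4.61
Gastrocnemius	C3	0.47	0.18	1.03
Gluteus maximus	C3	1.44	0.14	2.64
Iliopsoas	C3	4.01	0.19	2.86
Rectus femoris	C3	0.83	0.16	1.21
Semimembranosus	C3	0.23	0.59	2.08
Semitendinosus	C3	0.75	1.03	3.16
Tibialis anterior	C3	2.03	0.09	1.67
Triceps	C3	0.76	1.38	0.91
Vastus lateralis	C3	0.61	0.46	1.32
Vastus medialis	C3	3.56	0.72	2.80
Extensor digiti minimi	C4	4.12	2.89	31.5
Extensor digitorum communis	C4	3.85	0.84	33.33
Flexor digitorum superficialis	C4	3.15	2.94	39.19
Tibialis posterior	C4	13.08	3.20	27.88
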