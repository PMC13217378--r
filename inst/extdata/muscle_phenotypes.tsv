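name	wet_weight	slow_fiber_pct	muscle_length	fiber_length	pennation_angle	pcsa
Extensor carpi radialis	0.0062	26.0	7.76	5.60	26.40	1.26
Extensor carpi ulnaris	0.0031	38.8	6.49	2.74	20.80	1.72
Extensor digitorum longus	0.0041	10.9	12.20	6.20	8.30	1.80
Flexor carpi radialis	0.0042	29.2	7.52	3.67	15.02	1.27
Flexor carpi ulnaris	0.0042	38.6	8.19	3.80	20.95	2.29
Palmaris longus	0.0039	43.9	5.96	3.62	24.65	0.91
Plantaris	0.0088	17.7	13.50	5.30	14.30	2.80
Soleus	0.0068	69.4	11.20	8.10	8.50	0.90
Biceps femoris	0.1118	21.0	19.00	15.00	0	11.30
Flexor digitorum profundus (lower)	0.0281	19.3				
Flexor digitorum profundus (upper)	0.0076	21.5				
Gastrocnemius	0.1206	25.4				
Gluteus maximus	0.0881	34.1				
Iliopsoas	0.0433	46.7				
Rectus femoris	0.0614	17.7	14.20	6.10	13.20	11.4
Semimembranosus	0.0843	21.2	18.60	17.10	0	1.20
Semitendinosus	0.0471	20.4				
Tibialis anterior	0.0449	16.9	12.90	7.90	11.70	5.30
Triceps	0.0775	24.5				
Vastus lateralis	0.0635	16.4	15.40	9.10	7.20	8.50
Vastus medialis	0.0282	19.7	15.30	9.00	7.20	8.60
Extensor digiti minimi	0.0020	59.6				
Extensor digitorum communis	0.0042	24.0	7.81	3.84	18.56	0.67
Flexor digitorum superficialis	0.0062	40.2	9.99	2.50	18.96	2.84
Tibialis posterior	0.0033	18.5	8.00	5.10	3.20	0.40
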