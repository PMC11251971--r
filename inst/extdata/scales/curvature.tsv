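#name curvature
#k 2
#units degrees
#citation Bolshoy A, McNamara P, Harrington RE, Trifonov EN (1991) Curved DNA without A-A: experimental estimation of all 16 DNA wedge angles. PNAS 88:2312-2316. Twist angles: Kabsch W, Sander C, Trifonov EN (1982) Nucleic Acids Res 10:1097-1104.
#strand_symmetric false
#window_len 21
AA	7.20	-154.0	35.62
AC	1.10	143.0	34.40
AG	8.40	2.0	27.70
AT	2.60	0.0	31.50
CA	3.50	-64.0	34.50
CC	2.10	-57.0	33.67
CG	6.70	0.0	29.80
CT	8.40	-2.0	27.70
GA	5.30	120.0	36.90
GC	5.00	180.0	40.00
GG	2.10	57.0	33.67
GT	1.10	-143.0	34.40
TA	0.90	0.0	36.00
TC	5.30	-120.0	36.90
TG	3.50	64.0	34.50
TT	7.20	154.0	35.62
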