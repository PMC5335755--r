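BEGIN IONS
TITLE=example scan=101
SCANS=101
RTINSECONDS=623.4
PEPMASS=500.25
CHARGE=2+
120.0810 1500.0
175.1190 8200.5
276.1550 950.2
333.1770 4100.0
502.2880 2300.7
END IONS
BEGIN IONS
TITLE=example scan=102
SCANS=102
RTINSECONDS=624.9
PEPMASS=600.10
CHARGE=3+
101.0710 300.0
129.1020 5600.1
244.1660 780.4
358.2090 1900.9
471.2930 640.8
586.3360 2250.3
END IONS
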