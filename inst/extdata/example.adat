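^HEADER
!AdatVersion	1.0
!AssayType	synthetic-fixture
^COL_DATA
SeqId	SL0001	SL0002	SL0003	SL0004
Target	TGT0001	TGT0002	TGT0003	TGT0004
IsHuman	TRUE	TRUE	TRUE	TRUE
IsValidated	TRUE	TRUE	TRUE	TRUE
AffinityKd	0.5	1.2	0.8	2.5
^ROW_DATA
!Fields	PatientId	SampleId	TimeYears
^TABLE_BEGIN
P0001	P0001-V01	0	1023.5	880.2	1500	760.1
P0001	P0001-V02	0.52	1100.8	905.4	1488.2	770
P0002	P0002-V01	0	998.7	860	1520.9	755.3
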