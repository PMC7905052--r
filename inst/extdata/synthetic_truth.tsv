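C0001	C0001
C0002	C0002
C0003	C0003
C0004	C0004
C0005	C0005
C0006	C0006
C0007	C0007
C0008	C0008
C0009	C0009
C0010	C0010
C0011	C0011
C0012	C0012
C0013	C0013
C0014	C0014
C0015	C0015
C0016	C0016
C0017	C0017
C0018	C0018
C0019	C0019
C0020	C0020
C0021	C0021
C0022	C0022
C0023	C0023
C0024	C0024
C0025	C0025
C0026	C0026
C0027	C0027
C0028	C0028
C0029	C0029
C0030	C0030
C0031	C0031
C0032	C0032
C0033	C0033
C0034	C0034
C0035	C0035
C0036	C0036
C0037	C0037
C0038	C0038
C0039	C0039
C0040	C0040
C0041	C0041
C0042	C0042
C0043	C0043
C0044	C0044
C0045	C0045
C0046	C0046
C0047	C0047
C0048	C0048
C0049	C0049
C0050	C0050
C0051	C0051
C0052	C0052
C0053	C0053
C0054	C0054
C0055	C0055
C0056	C0056
C0057	C0057
C0058	C0058
C0059	C0059
C0060	C0060
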