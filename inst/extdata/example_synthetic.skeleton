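3
1
72057594037931101 0 0 0 0 0 0 0 0 0
25
0.000000 0.000000 0.000000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.000000 0.000000 0.300000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.350000 0.000000 0.550000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.334450 0.044213 0.505000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.200000 0.000000 0.450000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.289184 0.084498 0.460000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.218221 0.117275 0.415000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.127869 0.139631 0.370000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.200000 0.000000 0.450000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.026156 0.149581 0.325000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.077882 0.146239 0.280000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.175000 0.129904 0.235000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.256568 0.102026 0.190000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.315339 0.065083 0.145000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.346091 0.022356 0.100000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.346091 -0.022356 0.055000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.315339 -0.065083 0.010000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.256568 -0.102026 -0.035000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.175000 -0.129904 -0.080000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.077882 -0.146239 -0.125000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.026156 -0.149581 -0.170000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.127869 -0.139631 -0.215000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.218221 -0.117275 -0.260000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.289184 -0.084498 -0.305000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.334450 -0.044213 -0.350000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
1
72057594037931101 0 0 0 0 0 0 0 0 0
25
0.020000 0.000000 0.010000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.020000 0.000000 0.310000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.370000 0.000000 0.560000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.354450 0.044213 0.515000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.220000 0.000000 0.460000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.309184 0.084498 0.470000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.238221 0.117275 0.425000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.147869 0.139631 0.380000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.180000 0.000000 0.460000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.046156 0.149581 0.335000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.057882 0.146239 0.290000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.155000 0.129904 0.245000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.236568 0.102026 0.200000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.295339 0.065083 0.155000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.326091 0.022356 0.110000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.326091 -0.022356 0.065000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.295339 -0.065083 0.020000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.236568 -0.102026 -0.025000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.155000 -0.129904 -0.070000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.057882 -0.146239 -0.115000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.046156 -0.149581 -0.160000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.147869 -0.139631 -0.205000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.238221 -0.117275 -0.250000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.309184 -0.084498 -0.295000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.354450 -0.044213 -0.340000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
1
72057594037931101 0 0 0 0 0 0 0 0 0
25
0.040000 0.000000 0.020000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.040000 0.000000 0.320000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.390000 0.000000 0.570000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.374450 0.044213 0.525000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.240000 0.000000 0.470000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.329184 0.084498 0.480000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.258221 0.117275 0.435000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.167869 0.139631 0.390000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.160000 0.000000 0.470000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.066156 0.149581 0.345000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.037882 0.146239 0.300000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.135000 0.129904 0.255000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.216568 0.102026 0.210000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.275339 0.065083 0.165000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.306091 0.022356 0.120000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.306091 -0.022356 0.075000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.275339 -0.065083 0.030000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.216568 -0.102026 -0.015000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.135000 -0.129904 -0.060000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
-0.037882 -0.146239 -0.105000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.066156 -0.149581 -0.150000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.167869 -0.139631 -0.195000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.258221 -0.117275 -0.240000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.329184 -0.084498 -0.285000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
0.374450 -0.044213 -0.330000 0.0 0.0 0.0 0.0 0.0 0.0 0.0 0.0 2
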