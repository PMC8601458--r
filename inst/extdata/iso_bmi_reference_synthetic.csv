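sex,age_years,bmi_child,bmi_adult_equiv
F,6,9.18,13.02
F,6,12.240000000000002,17.36
F,6,15.3,21.7
F,6,18.36,26.04
F,6,22.950000000000003,32.55
F,6,30.6,43.4
F,7,9.4542,13.02
F,7,12.605600000000003,17.36
F,7,15.757000000000001,21.7
F,7,18.9084,26.04
F,7,23.6355,32.55
F,7,31.514000000000003,43.4
F,8,9.7284,13.02
F,8,12.971200000000003,17.36
F,8,16.214000000000002,21.7
F,8,19.4568,26.04
F,8,24.321000000000005,32.55
F,8,32.428000000000004,43.4
F,9,10.0026,13.02
F,9,13.3368,17.36
F,9,16.671,21.7
F,9,20.0052,26.04
F,9,25.0065,32.55
F,9,33.342,43.4
F,10,10.2768,13.02
F,10,13.7024,17.36
F,10,17.128,21.7
F,10,20.5536,26.04
F,10,25.692,32.55
F,10,34.256,43.4
F,11,10.551,13.02
F,11,14.068000000000001,17.36
F,11,17.585,21.7
F,11,21.102,26.04
F,11,26.3775,32.55
F,11,35.17,43.4
F,12,10.8252,13.02
F,12,14.433600000000002,17.36
F,12,18.042,21.7
F,12,21.6504,26.04
F,12,27.063000000000002,32.55
F,12,36.084,43.4
F,13,11.099400000000001,13.02
F,13,14.799200000000003,17.36
F,13,18.499000000000002,21.7
F,13,22.198800000000002,26.04
F,13,27.748500000000003,32.55
F,13,36.998000000000005,43.4
F,14,11.3736,13.02
F,14,15.1648,17.36
F,14,18.956,21.7
F,14,22.7472,26.04
F,14,28.433999999999997,32.55
F,14,37.912,43.4
F,15,11.6478,13.02
F,15,15.5304,17.36
F,15,19.413,21.7
F,15,23.2956,26.04
F,15,29.119500000000002,32.55
F,15,38.826,43.4
F,16,11.922,13.02
F,16,15.896,17.36
F,16,19.87,21.7
F,16,23.844,26.04
F,16,29.805,32.55
F,16,39.74,43.4
F,17,12.196200000000001,13.02
F,17,16.2616,17.36
F,17,20.327,21.7
F,17,24.392400000000002,26.04
F,17,30.490500000000004,32.55
F,17,40.654,43.4
F,18,12.4704,13.02
F,18,16.6272,17.36
F,18,20.784,21.7
F,18,24.9408,26.04
F,18,31.176,32.55
F,18,41.568,43.4
F,19,12.7446,13.02
F,19,16.9928,17.36
F,19,21.241,21.7
F,19,25.4892,26.04
F,19,31.8615,32.55
F,19,42.482,43.4
F,20,13.0188,13.02
F,20,17.3584,17.36
F,20,21.698,21.7
F,20,26.0376,26.04
F,20,32.547,32.55
F,20,43.396,43.4
M,6,9.299999999999999,13.02
M,6,12.4,17.36
M,6,15.5,21.7
M,6,18.599999999999998,26.04
M,6,23.25,32.55
M,6,31,43.4
M,7,9.5658,13.02
M,7,12.7544,17.36
M,7,15.943,21.7
M,7,19.1316,26.04
M,7,23.9145,32.55
M,7,31.886,43.4
M,8,9.8316,13.02
M,8,13.1088,17.36
M,8,16.386,21.7
M,8,19.6632,26.04
M,8,24.579,32.55
M,8,32.772,43.4
M,9,10.0974,13.02
M,9,13.4632,17.36
M,9,16.829,21.7
M,9,20.1948,26.04
M,9,25.2435,32.55
M,9,33.658,43.4
M,10,10.363199999999999,13.02
M,10,13.817599999999999,17.36
M,10,17.272,21.7
M,10,20.726399999999998,26.04
M,10,25.907999999999998,32.55
M,10,34.544,43.4
M,11,10.629,13.02
M,11,14.172,17.36
M,11,17.715,21.7
M,11,21.258,26.04
M,11,26.572499999999998,32.55
M,11,35.43,43.4
M,12,10.8948,13.02
M,12,14.526400000000002,17.36
M,12,18.158,21.7
M,12,21.7896,26.04
M,12,27.237000000000002,32.55
M,12,36.316,43.4
M,13,11.160599999999999,13.02
M,13,14.8808,17.36
M,13,18.601,21.7
M,13,22.321199999999997,26.04
M,13,27.9015,32.55
M,13,37.202,43.4
M,14,11.4264,13.02
M,14,15.2352,17.36
M,14,19.044,21.7
M,14,22.8528,26.04
M,14,28.566000000000003,32.55
M,14,38.088,43.4
M,15,11.692200000000001,13.02
M,15,15.589600000000003,17.36
M,15,19.487000000000002,21.7
M,15,23.384400000000003,26.04
M,15,29.230500000000003,32.55
M,15,38.974000000000004,43.4
M,16,11.958,13.02
M,16,15.944,17.36
M,16,19.93,21.7
M,16,23.916,26.04
M,16,29.895,32.55
M,16,39.86,43.4
M,17,12.2238,13.02
M,17,16.2984,17.36
M,17,20.373,21.7
M,17,24.4476,26.04
M,17,30.5595,32.55
M,17,40.746,43.4
M,18,12.4896,13.02
M,18,16.6528,17.36
M,18,20.816,21.7
M,18,24.9792,26.04
M,18,31.223999999999997,32.55
M,18,41.632,43.4
M,19,12.7554,13.02
M,19,17.0072,17.36
M,19,21.259,21.7
M,19,25.5108,26.04
M,19,31.8885,32.55
M,19,42.518,43.4
M,20,13.021199999999999,13.02
M,20,17.3616,17.36
M,20,21.701999999999998,21.7
M,20,26.042399999999997,26.04
M,20,32.553,32.55
M,20,43.403999999999996,43.4
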