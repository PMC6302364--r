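id,siteA,siteB,siteC,truth
report_01,0.9884315117,0.01156289515,5.59317347e-06,siteA
report_02,0.8530897755,0.1468783427,3.188175186e-05,siteA
report_03,0.9797793674,0.020216368,4.264608109e-06,siteA
report_04,0.0200072157,0.9402166216,0.03977616266,siteB
report_05,0.9007369728,0.09924158553,2.144169126e-05,siteA
report_06,0.0004747270983,0.5705193404,0.4290059325,siteB
report_07,0.995627863,0.004370834909,1.302042686e-06,siteA
report_08,9.009069807e-07,0.001320453222,0.9986786459,siteC
report_09,0.05473576709,0.9335476269,0.01171660605,siteB
report_10,0.1189035332,0.8617596201,0.01933684667,siteB
report_11,0.9087402235,0.09119986505,5.991143798e-05,siteA
report_12,0.006934928427,0.714274772,0.2787902996,siteC
report_13,0.9955229551,0.004476636976,4.079079382e-07,siteA
report_14,0.06505899903,0.9179800713,0.0169609297,siteC
report_15,0.2811411463,0.7169879748,0.001870878903,siteA
report_16,9.033361837e-06,0.04160505747,0.9583859092,siteC
report_17,0.5341966016,0.4644844256,0.001318972852,siteB
report_18,0.9996512412,0.0003487085975,5.022042168e-08,siteA
report_19,0.9991028035,0.0008970163713,1.801344037e-07,siteA
report_20,0.7849152232,0.214693806,0.0003909707958,siteA
report_21,0.0001607869653,0.1811669575,0.8186722555,siteC
report_22,0.09143417972,0.9005391931,0.008026627135,siteA
report_23,0.9765363279,0.02345929017,4.381954656e-06,siteA
report_24,3.011458371e-10,2.177196935e-06,0.9999978225,siteC
report_25,0.2117097201,0.7675974867,0.02069279324,siteB
report_26,0.1239232027,0.8704017572,0.005675040088,siteA
report_27,0.8856604518,0.114310054,2.949428068e-05,siteA
report_28,0.9994294604,0.0005703755183,1.640438001e-07,siteA
report_29,0.01329520091,0.9697647888,0.0169400103,siteB
report_30,0.0001345712625,0.03201864895,0.9678467798,siteC
report_31,0.2260537516,0.7734878203,0.0004584280855,siteA
report_32,0.008640383962,0.9350144049,0.05634521109,siteC
report_33,0.7452923984,0.2545684075,0.0001391940328,siteA
report_34,0.1579274488,0.8401023606,0.001970190641,siteB
report_35,6.995862697e-05,0.05582015159,0.9441098898,siteC
report_36,0.5478055448,0.4519515124,0.0002429428132,siteA
report_37,0.9963279601,0.003670954374,1.085489712e-06,siteA
report_38,0.8436084397,0.1563387662,5.279407689e-05,siteA
report_39,0.3319010912,0.6672150588,0.0008838499246,siteA
report_40,0.0001966149388,0.06562414179,0.9341792433,siteC
report_41,0.9750650282,0.02492019325,1.477857695e-05,siteA
report_42,6.522612343e-07,0.004056580825,0.9959427669,siteC
report_43,0.0921566041,0.8973896376,0.01045375834,siteB
report_44,4.456018845e-08,0.0001457687948,0.9998541866,siteC
report_45,0.0001470549107,0.146894811,0.8529581341,siteC
report_46,0.999801601,0.0001983847857,1.419094241e-08,siteA
report_47,0.9999998403,1.596535591e-07,4.038642206e-12,siteA
report_48,0.4454958555,0.5538264049,0.0006777395537,siteB
report_49,0.8494275896,0.1504761789,9.62315369e-05,siteA
report_50,0.9941117151,0.005887655055,6.298413575e-07,siteA
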