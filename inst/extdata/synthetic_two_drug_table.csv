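block_id,drug_1,drug_2,conc_1,conc_2,response,conc_unit_1,conc_unit_2
synthetic_pair,A,B,0,0,-1.8793614322269971,uM,uM
synthetic_pair,A,B,0.1,0,9.64183906357534,uM,uM
synthetic_pair,A,B,0.31622776601683794,0,21.518421497974074,uM,uM
synthetic_pair,A,B,1,0,54.78584240641338,uM,uM
synthetic_pair,A,B,3.1622776601683795,0,76.96321598024186,uM,uM
synthetic_pair,A,B,10,0,88.44768575673686,uM,uM
synthetic_pair,A,B,0,0.1,10.55319624819455,uM,uM
synthetic_pair,A,B,0.1,0.1,29.570346016214106,uM,uM
synthetic_pair,A,B,0.31622776601683794,0.1,42.65944163241886,uM,uM
synthetic_pair,A,B,1,0.1,63.629289383985466,uM,uM
synthetic_pair,A,B,3.1622776601683795,0.1,92.69415501880324,uM,uM
synthetic_pair,A,B,10,0.1,102.90506689931694,uM,uM
synthetic_pair,A,B,0,0.31622776601683794,22.161585593578803,uM,uM
synthetic_pair,A,B,0.1,0.31622776601683794,34.287997915925885,uM,uM
synthetic_pair,A,B,0.31622776601683794,0.31622776601683794,55.65325349932758,uM,uM
synthetic_pair,A,B,1,0.31622776601683794,71.87785284055643,uM,uM
synthetic_pair,A,B,3.1622776601683795,0.31622776601683794,91.69827580100912,uM,uM
synthetic_pair,A,B,10,0.31622776601683794,105.92471838980173,uM,uM
synthetic_pair,A,B,0,1,52.46366358529426,uM,uM
synthetic_pair,A,B,0.1,1,66.32715850910706,uM,uM
synthetic_pair,A,B,0.31622776601683794,1,74.76958578242676,uM,uM
synthetic_pair,A,B,1,1,87.34640890219319,uM,uM
synthetic_pair,A,B,3.1622776601683795,1,98.21104128249345,uM,uM
synthetic_pair,A,B,10,1,99.48649036695535,uM,uM
synthetic_pair,A,B,0,3.1622776601683795,77.8341699084799,uM,uM
synthetic_pair,A,B,0.1,3.1622776601683795,87.9904252948637,uM,uM
synthetic_pair,A,B,0.31622776601683794,3.1622776601683795,91.27946007018997,uM,uM
synthetic_pair,A,B,1,3.1622776601683795,93.57508918070006,uM,uM
synthetic_pair,A,B,3.1622776601683795,3.1622776601683795,102.79339590916396,uM,uM
synthetic_pair,A,B,10,3.1622776601683795,109.06970583194419,uM,uM
synthetic_pair,A,B,0,10,94.98512956367804,uM,uM
synthetic_pair,A,B,0.1,10,101.42717400805365,uM,uM
synthetic_pair,A,B,0.31622776601683794,10,104.25622459242393,uM,uM
synthetic_pair,A,B,1,10,105.29313033279675,uM,uM
synthetic_pair,A,B,3.1622776601683795,10,103.68470248085926,uM,uM
synthetic_pair,A,B,10,10,107.92857002910922,uM,uM
synthetic_pair,A,B,0,0,-1.1828698611310478,uM,uM
synthetic_pair,A,B,0.1,0,8.912968900775537,uM,uM
synthetic_pair,A,B,0.31622776601683794,0,27.325383451155865,uM,uM
synthetic_pair,A,B,1,0,52.28952724537264,uM,uM
synthetic_pair,A,B,3.1622776601683795,0,75.48112187603502,uM,uM
synthetic_pair,A,B,10,0,90.14900586868139,uM,uM
synthetic_pair,A,B,0,0.1,11.181799217123306,uM,uM
synthetic_pair,A,B,0.1,0.1,29.025361496847424,uM,uM
synthetic_pair,A,B,0.31622776601683794,0.1,38.865830493809824,uM,uM
synthetic_pair,A,B,1,0.1,62.42296907456818,uM,uM
synthetic_pair,A,B,3.1622776601683795,0.1,89.25255739986119,uM,uM
synthetic_pair,A,B,10,0.1,104.04113596362889,uM,uM
synthetic_pair,A,B,0,0.31622776601683794,23.688268698753532,uM,uM
synthetic_pair,A,B,0.1,0.31622776601683794,43.575420756821025,uM,uM
synthetic_pair,A,B,0.31622776601683794,0.31622776601683794,53.47277838599946,uM,uM
synthetic_pair,A,B,1,0.31622776601683794,70.17657448784979,uM,uM
synthetic_pair,A,B,3.1622776601683795,0.31622776601683794,92.77020566457924,uM,uM
synthetic_pair,A,B,10,0.31622776601683794,99.70512046950346,uM,uM
synthetic_pair,A,B,0,1,54.29907110510312,uM,uM
synthetic_pair,A,B,0.1,1,70.48665424097211,uM,uM
synthetic_pair,A,B,0.31622776601683794,1,70.91098923820257,uM,uM
synthetic_pair,A,B,1,1,81.8675961210504,uM,uM
synthetic_pair,A,B,3.1622776601683795,1,99.69650521472514,uM,uM
synthetic_pair,A,B,10,1,105.04938164290299,uM,uM
synthetic_pair,A,B,0,3.1622776601683795,83.1795459463101,uM,uM
synthetic_pair,A,B,0.1,3.1622776601683795,88.04109150525119,uM,uM
synthetic_pair,A,B,0.31622776601683794,3.1622776601683795,93.81606467765829,uM,uM
synthetic_pair,A,B,1,3.1622776601683795,98.07135280873989,uM,uM
synthetic_pair,A,B,3.1622776601683795,3.1622776601683795,101.99802644784262,uM,uM
synthetic_pair,A,B,10,3.1622776601683795,108.38225804988811,uM,uM
synthetic_pair,A,B,0,10,85.49421502241779,uM,uM
synthetic_pair,A,B,0.1,10,106.13220177477129,uM,uM
synthetic_pair,A,B,0.31622776601683794,10,103.55296977238153,uM,uM
synthetic_pair,A,B,1,10,111.97238046563191,uM,uM
synthetic_pair,A,B,3.1622776601683795,10,109.24240973804406,uM,uM
synthetic_pair,A,B,10,10,107.04371442624283,uM,uM
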