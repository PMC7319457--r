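block_id,synthetic_pair
drug_row,A,unit,uM
drug_col,B,unit,uM
conc,0,0.10000000000000001,0.31622776601683794,1,3.1622776601683795,10
0,-1.8793614322269971,10.553196248194549,22.161585593578803,52.463663585294263,77.834169908479893,94.985129563678043
0.10000000000000001,9.6418390635753397,29.570346016214106,34.287997915925885,66.327158509107065,87.990425294863698,101.42717400805365
0.31622776601683794,21.518421497974074,42.659441632418861,55.653253499327583,74.769585782426759,91.27946007018997,104.25622459242393
1,54.78584240641338,63.629289383985466,71.877852840556429,87.34640890219319,93.575089180700061,105.29313033279675
3.1622776601683795,76.963215980241856,92.694155018803244,91.698275801009117,98.211041282493454,102.79339590916396,103.68470248085926
10,88.44768575673686,102.90506689931694,105.92471838980173,99.486490366955351,109.06970583194419,107.92857002910922

block_id,synthetic_pair
drug_row,A,unit,uM
drug_col,B,unit,uM
conc,0,0.10000000000000001,0.31622776601683794,1,3.1622776601683795,10
0,-1.1828698611310478,11.181799217123306,23.688268698753532,54.299071105103117,83.1795459463101,85.494215022417791
0.10000000000000001,8.9129689007755371,29.025361496847424,43.575420756821025,70.486654240972115,88.041091505251188,106.13220177477129
0.31622776601683794,27.325383451155865,38.865830493809824,53.472778385999462,70.910989238202575,93.816064677658289,103.55296977238153
1,52.289527245372639,62.422969074568179,70.176574487849791,81.867596121050397,98.071352808739888,111.97238046563191
3.1622776601683795,75.481121876035019,89.252557399861189,92.770205664579237,99.696505214725136,101.99802644784262,109.24240973804406
10,90.149005868681385,104.04113596362889,99.705120469503456,105.04938164290299,108.38225804988811,107.04371442624283

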