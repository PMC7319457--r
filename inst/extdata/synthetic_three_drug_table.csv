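block_id,drug_1,drug_2,drug_3,conc_1,conc_2,conc_3,response,conc_unit_1,conc_unit_2,conc_unit_3
synthetic_triplet,A,B,C,0,0,0,-2.690743639874944,uM,uM,uM
synthetic_triplet,A,B,C,0.3,0,0,23.631470630863298,uM,uM,uM
synthetic_triplet,A,B,C,1,0,0,54.76353599362647,uM,uM,uM
synthetic_triplet,A,B,C,3,0,0,71.60887297726114,uM,uM,uM
synthetic_triplet,A,B,C,0,0.3,0,22.836167807270105,uM,uM,uM
synthetic_triplet,A,B,C,0.3,0.3,0,41.225663220007185,uM,uM,uM
synthetic_triplet,A,B,C,1,0.3,0,63.66232572627675,uM,uM,uM
synthetic_triplet,A,B,C,3,0.3,0,80.05013669671524,uM,uM,uM
synthetic_triplet,A,B,C,0,1,0,55.95342180995878,uM,uM,uM
synthetic_triplet,A,B,C,0.3,1,0,61.12210050210255,uM,uM,uM
synthetic_triplet,A,B,C,1,1,0,76.25295225237767,uM,uM,uM
synthetic_triplet,A,B,C,3,1,0,90.44525833239099,uM,uM,uM
synthetic_triplet,A,B,C,0,3,0,73.82191393348856,uM,uM,uM
synthetic_triplet,A,B,C,0.3,3,0,77.65022383838404,uM,uM,uM
synthetic_triplet,A,B,C,1,3,0,92.84668688092572,uM,uM,uM
synthetic_triplet,A,B,C,3,3,0,86.8167927461845,uM,uM,uM
synthetic_triplet,A,B,C,0,0,0.3,25.712736819686867,uM,uM,uM
synthetic_triplet,A,B,C,0.3,0,0.3,40.93582252090958,uM,uM,uM
synthetic_triplet,A,B,C,1,0,0.3,64.5769476148428,uM,uM,uM
synthetic_triplet,A,B,C,3,0,0.3,82.06602623284962,uM,uM,uM
synthetic_triplet,A,B,C,0,0.3,0.3,47.10085998261134,uM,uM,uM
synthetic_triplet,A,B,C,0.3,0.3,0.3,60.88360897711753,uM,uM,uM
synthetic_triplet,A,B,C,1,0.3,0.3,85.18311578430216,uM,uM,uM
synthetic_triplet,A,B,C,3,0.3,0.3,101.07105551838573,uM,uM,uM
synthetic_triplet,A,B,C,0,1,0.3,61.55327486894598,uM,uM,uM
synthetic_triplet,A,B,C,0.3,1,0.3,73.05908201989357,uM,uM,uM
synthetic_triplet,A,B,C,1,1,0.3,92.20094267707162,uM,uM,uM
synthetic_triplet,A,B,C,3,1,0.3,98.59494087872118,uM,uM,uM
synthetic_triplet,A,B,C,0,3,0.3,83.14584058012971,uM,uM,uM
synthetic_triplet,A,B,C,0.3,3,0.3,96.07601072224801,uM,uM,uM
synthetic_triplet,A,B,C,1,3,0.3,102.60143119590175,uM,uM,uM
synthetic_triplet,A,B,C,3,3,0.3,106.14918889560063,uM,uM,uM
synthetic_triplet,A,B,C,0,0,1,53.22849306143601,uM,uM,uM
synthetic_triplet,A,B,C,0.3,0,1,60.685988376996804,uM,uM,uM
synthetic_triplet,A,B,C,1,0,1,72.66997417806073,uM,uM,uM
synthetic_triplet,A,B,C,3,0,1,85.71301850392466,uM,uM,uM
synthetic_triplet,A,B,C,0,0.3,1,56.36052220102344,uM,uM,uM
synthetic_triplet,A,B,C,0.3,0.3,1,77.70644774414089,uM,uM,uM
synthetic_triplet,A,B,C,1,0.3,1,89.09204502452937,uM,uM,uM
synthetic_triplet,A,B,C,3,0.3,1,99.64507768261484,uM,uM,uM
synthetic_triplet,A,B,C,0,1,1,73.84924131470567,uM,uM,uM
synthetic_triplet,A,B,C,0.3,1,1,84.89192124372939,uM,uM,uM
synthetic_triplet,A,B,C,1,1,1,94.97488481959317,uM,uM,uM
synthetic_triplet,A,B,C,3,1,1,109.46064240204294,uM,uM,uM
synthetic_triplet,A,B,C,0,3,1,89.36748179036222,uM,uM,uM
synthetic_triplet,A,B,C,0.3,3,1,106.35737669135632,uM,uM,uM
synthetic_triplet,A,B,C,1,3,1,102.83354882547565,uM,uM,uM
synthetic_triplet,A,B,C,3,3,1,106.60246729439773,uM,uM,uM
synthetic_triplet,A,B,C,0,0,3,74.44751564534621,uM,uM,uM
synthetic_triplet,A,B,C,0.3,0,3,77.17292747330853,uM,uM,uM
synthetic_triplet,A,B,C,1,0,3,84.98513855719388,uM,uM,uM
synthetic_triplet,A,B,C,3,0,3,99.94890406719371,uM,uM,uM
synthetic_triplet,A,B,C,0,0.3,3,79.0824896092033,uM,uM,uM
synthetic_triplet,A,B,C,0.3,0.3,3,99.03424712726874,uM,uM,uM
synthetic_triplet,A,B,C,1,0.3,3,97.24189750363044,uM,uM,uM
synthetic_triplet,A,B,C,3,0.3,3,99.29467296796572,uM,uM,uM
synthetic_triplet,A,B,C,0,1,3,86.53108671872009,uM,uM,uM
synthetic_triplet,A,B,C,0.3,1,3,103.19220296504128,uM,uM,uM
synthetic_triplet,A,B,C,1,1,3,107.16768940820225,uM,uM,uM
synthetic_triplet,A,B,C,3,1,3,111.88985630197799,uM,uM,uM
synthetic_triplet,A,B,C,0,3,3,88.38527337970544,uM,uM,uM
synthetic_triplet,A,B,C,0.3,3,3,111.28603524857343,uM,uM,uM
synthetic_triplet,A,B,C,1,3,3,104.76556700101835,uM,uM,uM
synthetic_triplet,A,B,C,3,3,3,108.91199428768037,uM,uM,uM
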