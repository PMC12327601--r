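name,mode,charge,multimer,mass_shift
[M+H]+,positive,1,1,1.007276
[M+NH4]+,positive,1,1,18.033823
[M+Na]+,positive,1,1,22.989218
[M+K]+,positive,1,1,38.963158
[M+Li]+,positive,1,1,7.016004
[M+CH3OH+H]+,positive,1,1,33.033489
[M+ACN+H]+,positive,1,1,42.033823
[M+ACN+Na]+,positive,1,1,64.015765
[M+2ACN+H]+,positive,1,1,83.06037
[M+IsoProp+H]+,positive,1,1,61.06534
[M+DMSO+H]+,positive,1,1,79.02122
[M+H-H2O]+,positive,1,1,-17.003289
[M+H-2H2O]+,positive,1,1,-35.013854
[M+2Na-H]+,positive,1,1,44.97116
[M+2K-H]+,positive,1,1,76.91904
[2M+H]+,positive,1,2,1.007276
[2M+NH4]+,positive,1,2,18.033823
[2M+Na]+,positive,1,2,22.989218
[2M+K]+,positive,1,2,38.963158
[2M+ACN+H]+,positive,1,2,42.033823
[2M+ACN+Na]+,positive,1,2,64.015765
[M+2H]2+,positive,2,1,2.014552
[M+H+Na]2+,positive,2,1,23.996494
[M+H+NH4]2+,positive,2,1,19.041099
[M+2Na]2+,positive,2,1,45.978436
[M+3H]3+,positive,3,1,3.021828
[M-H]-,negative,-1,1,-1.007276
[M-H2O-H]-,negative,-1,1,-19.017841
[M+Na-2H]-,negative,-1,1,20.974666
[M+K-2H]-,negative,-1,1,36.948606
[M+Cl]-,negative,-1,1,34.969402
[M+Br]-,negative,-1,1,78.918885
[M+F]-,negative,-1,1,18.998403
[M+FA-H]-,negative,-1,1,44.998201
[M+HAc-H]-,negative,-1,1,59.013851
[M+TFA-H]-,negative,-1,1,112.985586
[M+NO3]-,negative,-1,1,61.988366
[M+HSO4]-,negative,-1,1,96.960103
[M+H2PO4]-,negative,-1,1,96.969618
[2M-H]-,negative,-1,2,-1.007276
[2M+FA-H]-,negative,-1,2,44.998201
[2M+HAc-H]-,negative,-1,2,59.013851
[2M+Cl]-,negative,-1,2,34.969402
[2M+Na-2H]-,negative,-1,2,20.974666
[3M-H]-,negative,-1,3,-1.007276
[M-2H]2-,negative,-2,1,-2.014552
[2M-2H]2-,negative,-2,2,-2.014552
[M-3H]3-,negative,-3,1,-3.021828
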