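# Chromatographic retention factors (k) of the 21 quinolone major
# microspecies used for QSRR modeling: one representative ionization state
# per compound at the buffer pH shown. Gradient reversed-phase HPLC,
# dead time 2.9 min. The split column records the calibration/external
# assignment (16 train / 5 test); membership is reconstructed from the
# published prediction listing and is flagged as inferred.
compound,pH,k,split
Gatifloxacin,3.5,1.603,train
Gatifloxacin,6.5,1.566,train
Lomefloxacin,3.5,1.560,train
Lomefloxacin,6.5,0.920,train
Moxifloxacin,3.5,1.606,train
Moxifloxacin,6.5,1.749,train
Nadifloxacin,3.5,2.148,train
Nadifloxacin,8.2,1.685,train
Norfloxacin,3.5,1.162,train
Norfloxacin,6.5,1.158,test
Ofloxacin,3.5,1.176,train
Ofloxacin,8.2,1.885,test
Ciprofloxacin,3.5,1.363,train
Ciprofloxacin,6.5,1.153,train
Gemifloxacin,3.5,1.576,train
Gemifloxacin,6.5,1.584,train
Enrofloxacin,2.2,1.622,test
Enrofloxacin,8.2,1.973,train
Danofloxacin,3.5,1.551,test
Danofloxacin,8.2,1.668,train
Sparfloxacin,3.5,1.576,test
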