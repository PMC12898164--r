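term,mean,sd
dGvdw,-25.5808,4.1208
dGele,-103.3406,60.2447
dGpolar,106.1549,54.2322
dGnonpolar,-3.2582,0.3614
dGgas,-128.9214,59.6415
dGsolv,102.8967,54.2081
dGtotal,-26.0247,10.0893
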