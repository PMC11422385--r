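disease,train,validation,internal_test
GLAU,20823,3022,6003
AMD,1594,203,443
RVO,2859,411,860
DR,6224,832,1697
NORM,41108,5274,11433
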